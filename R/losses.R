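#' Loss weights of the composite training objective
#'
#' The training loss is the sum of a k-space term and an image-domain term,
#' `L = lambda1 * MSE(FFT(rec), FFT(gnd)) + lambda2 * L1 + lambda3 * MSE +
#' lambda4 * (1 - SSIM)`, all computed on the two-channel (real/imaginary)
#' view of the reconstruction and the fully sampled ground truth. The
#' defaults weight the image domain more heavily than k-space and emphasize
#' the structural (SSIM) term.
#'
#' @param lambda1 k-space MSE weight (default 0.25).
#' @param lambda2 image L1 weight (default 0.5).
#' @param lambda3 image MSE weight (default 0.5).
#' @param lambda4 SSIM term weight (default 1).
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(lambda1 = 0.25, lambda2 = 0.5, lambda3 = 0.5,
                         lambda4 = 1) {
  w <- list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
            lambda4 = lambda4)
  if (any(unlist(w) < 0)) stop("loss weights must be non-negative")
  structure(w, class = "loss_weights")
}

# 2D Gaussian window, normalized to unit sum
gaussian_window <- function(size = 11L, sigma = 1.5) {
  r <- seq_len(size) - (size + 1) / 2
  g <- exp(-r^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# Gaussian blur of an (H, W, 1, T) tensor node via the conv kernel
.op_blur <- function(x, win) {
  k <- ad_const(array(win, c(dim(win), 1L, 1L)))
  op_conv2d(x, k, NULL)
}

# local SSIM map of two (H, W, 1, T) tensor nodes (same-padding windows)
ssim_map_node <- function(a, b, data_range, window = gaussian_window()) {
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  mu_a <- .op_blur(a, window); mu_b <- .op_blur(b, window)
  mu_aa <- op_mul(mu_a, mu_a); mu_bb <- op_mul(mu_b, mu_b)
  mu_ab <- op_mul(mu_a, mu_b)
  s_aa <- op_sub(.op_blur(op_mul(a, a), window), mu_aa)
  s_bb <- op_sub(.op_blur(op_mul(b, b), window), mu_bb)
  s_ab <- op_sub(.op_blur(op_mul(a, b), window), mu_ab)
  num <- op_mul(op_addc(op_scale(mu_ab, 2), c1), op_addc(op_scale(s_ab, 2), c2))
  den <- op_mul(op_addc(op_add(mu_aa, mu_bb), c1),
                op_addc(op_add(s_aa, s_bb), c2))
  op_div(num, den)
}

#' Structural similarity index
#'
#' Mean of the local SSIM map computed with a Gaussian window (default
#' 11x11, sigma 1.5) and the standard stabilizers `C1 = (0.01 L)^2`,
#' `C2 = (0.03 L)^2` for data range `L`. Inputs may be single frames
#' (matrices) or frame sequences (`(T, H, W)` arrays); sequences return the
#' mean over all frames' maps. Windows use same-size zero padding, so the
#' map has one value per pixel.
#'
#' @param a,b real-valued images: matrices or `(T, H, W)` arrays.
#' @param data_range value range L of the data (positive).
#' @param window normalized 2D window matrix.
#' @return scalar in (-1, 1].
#' @export
ssim_index <- function(a, b, data_range, window = gaussian_window()) {
  mean(ssim_map(a, b, data_range, window))
}

#' @rdname ssim_index
#' @return `ssim_map`: the per-pixel local SSIM map (same shape as the
#'   input).
#' @export
ssim_map <- function(a, b, data_range, window = gaussian_window()) {
  if (!is.numeric(data_range) || data_range <= 0)
    stop("data_range must be positive")
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  as_seq <- function(x) {
    if (is.matrix(x)) x <- array(x, c(1L, dim(x)))
    array(aperm(x, c(2, 3, 1)), c(dim(x)[2], dim(x)[3], 1L, dim(x)[1]))
  }
  an <- ad_const(as_seq(a)); bn <- ad_const(as_seq(b))
  m <- ssim_map_node(an, bn, data_range, window)$value
  if (is.matrix(a)) m[, , 1, 1] else aperm(array(m, dim(m)[c(1, 2, 4)]), c(3, 1, 2))
}

# ---- tape losses (training) ----------------------------------------------

# rec: (H,W,2,T) node; gnd2: (H,W,2,T) array
kspace_loss_node <- function(rec, gnd2, w) {
  kd <- op_sub(op_fft2c_2ch(rec), ad_const(cplx_to_net(fft2c(net_to_cplx(gnd2)))))
  op_scale(op_mean(op_mul(kd, kd)), w$lambda1)
}

image_loss_node <- function(rec, gnd2, w, data_range = NULL) {
  if (is.null(data_range)) data_range <- max(abs(gnd2))
  gn <- ad_const(gnd2)
  d <- op_sub(rec, gn)
  l1 <- op_scale(op_mean(op_abs(d)), w$lambda2)
  l2 <- op_scale(op_mean(op_mul(d, d)), w$lambda3)
  ssim_ch <- function(ci) {
    op_mean(ssim_map_node(op_slice_c(rec, ci), ad_const(gnd2[, , ci, , drop = FALSE]),
                          data_range))
  }
  ssim_term <- op_scale(op_add(ssim_ch(1L), ssim_ch(2L)), 0.5)
  op_add(op_add(l1, l2), op_scale(op_addc(op_scale(ssim_term, -1), 1), w$lambda4))
}

total_loss_node <- function(rec, gnd2, w, data_range = NULL) {
  op_add(kspace_loss_node(rec, gnd2, w),
         image_loss_node(rec, gnd2, w, data_range))
}

# ---- numeric user-facing losses ------------------------------------------

.as_2ch <- function(x) {
  if (is.complex(x)) cplx_to_net(x) else x
}

#' Training loss terms
#'
#' `kspace_loss()` is the weighted mean squared error between the centered
#' orthonormal FFTs of the reconstruction and the ground truth (both in the
#' two-channel real/imaginary view). `image_loss()` is the weighted sum of
#' an L1 term, an MSE term and an SSIM term (`lambda4 * (1 - SSIM)`, with
#' SSIM computed separately on the real and imaginary channels and
#' averaged). `total_loss()` is their sum.
#'
#' @param rec,gnd reconstruction and fully sampled ground truth: complex
#'   `(T, H, W)` arrays or two-channel `(H, W, 2, T)` arrays.
#' @param w a [loss_weights()] object.
#' @param data_range SSIM data range; defaults to the maximum absolute
#'   ground-truth channel value.
#' @return scalar loss value.
#' @export
kspace_loss <- function(rec, gnd, w = loss_weights()) {
  rec <- .as_2ch(rec); gnd <- .as_2ch(gnd)
  if (!identical(dim(rec), dim(gnd))) stop("shape mismatch")
  kspace_loss_node(ad_const(rec), gnd, w)$value
}

#' @rdname kspace_loss
#' @export
image_loss <- function(rec, gnd, w = loss_weights(), data_range = NULL) {
  rec <- .as_2ch(rec); gnd <- .as_2ch(gnd)
  if (!identical(dim(rec), dim(gnd))) stop("shape mismatch")
  image_loss_node(ad_const(rec), gnd, w, data_range)$value
}

#' @rdname kspace_loss
#' @export
total_loss <- function(rec, gnd, w = loss_weights(), data_range = NULL) {
  rec <- .as_2ch(rec); gnd <- .as_2ch(gnd)
  if (!identical(dim(rec), dim(gnd))) stop("shape mismatch")
  total_loss_node(ad_const(rec), gnd, w, data_range)$value
}
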