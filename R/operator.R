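#' The undersampled multi-coil forward operator and its adjoint
#'
#' The acquisition model is `y = A x` with `A = M o F o S`: coil expansion by
#' the sensitivity maps, centered orthonormal 2D Fourier transform per frame
#' and coil, and row-wise undersampling by the mask. `adjoint_A()` is the
#' Hermitian adjoint `A^H` (mask, inverse Fourier, conjugate coil
#' combination); applied to the measured k-space it yields the zero-filled
#' reconstruction used to initialize the unrolled network.
#'
#' @param x complex image sequence `(T, H, W)`.
#' @param y complex multi-coil k-space `(T, C, H, W)`.
#' @param S coil sensitivity maps `(C, H, W)`.
#' @param mask a [make_mask()] object or binary pattern matrix `(H, W)`.
#' @return `forward_A`: masked k-space `(T, C, H, W)`; `adjoint_A`: a
#'   `(T, H, W)` image sequence.
#' @export
forward_A <- function(x, S, mask) {
  mask <- as_sampling_mask(mask)
  if (length(mask$acquired_rows) == 0L) stop("mask acquires no rows")
  if (!all(dim(x)[2:3] == c(mask$n_rows, mask$n_cols)))
    stop("image and mask shapes are inconsistent")
  apply_mask(fft2c(coil_expand(x, S)), mask)
}

#' @rdname forward_A
#' @export
adjoint_A <- function(y, S, mask) {
  mask <- as_sampling_mask(mask)
  if (!all(dim(y)[3:4] == c(mask$n_rows, mask$n_cols)))
    stop("k-space and mask shapes are inconsistent")
  coil_combine(ifft2c(apply_mask(y, mask)), S)
}

#' @rdname forward_A
#' @export
zero_filled_recon <- function(y, S, mask) adjoint_A(y, S, mask)

# zero the unacquired phase-encode rows of a (T,C,H,W) k-space array
apply_mask <- function(y, mask) {
  mask <- as_sampling_mask(mask)
  keep <- mask$acquired_rows + 1L
  out <- array(0i, dim(y))
  out[, , keep, ] <- y[, , keep, ]
  out
}

#' Data-consistency parameters
#'
#' Controls how the k-space data-consistency step blends the network output
#' with the measured samples at acquired locations. In `"hard"` mode the
#' measured values replace the network's values exactly (the infinite-weight
#' limit); in `"learnable"` mode a positive scalar weight `lambda0` blends
#' them as `(k + lambda0 * y) / (1 + lambda0)` and is stored as an
#' unconstrained log-value so gradient updates keep it positive.
#'
#' @param lambda0 positive blending weight (ignored in hard mode other than
#'   conceptually being infinite).
#' @param mode `"hard"` (default) or `"learnable"`.
#' @return an object of class `dc_params`.
#' @export
dc_params <- function(lambda0 = 1e4, mode = c("hard", "learnable")) {
  mode <- match.arg(mode)
  if (!is.numeric(lambda0) || lambda0 <= 0) stop("lambda0 must be positive")
  structure(list(log_lambda0 = log(lambda0), mode = mode), class = "dc_params")
}

#' Closed-form k-space data consistency
#'
#' Given the network's image estimate `z`, transforms it to multi-coil
#' k-space, keeps its values at unacquired locations (the network's
#' interpolation of the zero-filled region), and at acquired locations
#' either replaces them by the measurements (hard mode) or blends
#' `(k_z + lambda0 * y) / (1 + lambda0)`, then returns to a coil-combined
#' image. The Fourier/coil part of the forward model is applied without the
#' mask projection so that the unacquired k-space content of `z` is
#' retained.
#'
#' Because the conjugate coil combination is a projection onto the pixelwise
#' sensitivity span, the blended per-coil k-space (not the re-expanded
#' combined image) is the representation in which the acquired samples are
#' preserved exactly; request it with `return_kspace = TRUE`.
#'
#' @param z complex image sequence `(T, H, W)` (network output).
#' @inheritParams forward_A
#' @param dc a [dc_params()] object.
#' @param return_kspace also return the blended per-coil k-space.
#' @return a `(T, H, W)` complex image sequence, or (with
#'   `return_kspace = TRUE`) a list with `image` and `kspace`.
#' @export
data_consistency <- function(z, y, S, mask, dc = dc_params(),
                             return_kspace = FALSE) {
  mask <- as_sampling_mask(mask)
  if (!all(dim(z) == dim(y)[c(1, 3, 4)]))
    stop("image and k-space shapes are inconsistent")
  kz <- fft2c(coil_expand(z, S))
  keep <- mask$acquired_rows + 1L
  if (dc$mode == "hard") {
    kz[, , keep, ] <- y[, , keep, ]
  } else {
    l0 <- exp(dc$log_lambda0)
    kz[, , keep, ] <- (kz[, , keep, ] + l0 * y[, , keep, ]) / (1 + l0)
  }
  img <- coil_combine(ifft2c(kz), S)
  if (return_kspace) list(image = img, kspace = kz) else img
}

#' Normalize k-space by the peak image-domain magnitude
#'
#' Transforms the multi-coil k-space to coil images, takes the maximum
#' magnitude over all frames, coils and pixels as the scale, and divides the
#' k-space by it. The scale is returned so reconstructions can be mapped
#' back to the physical value range.
#'
#' @param y complex multi-coil k-space `(T, C, H, W)`.
#' @return list with elements `y` (normalized k-space) and `scale`.
#' @export
maxabs_normalize <- function(y) {
  scale <- max(Mod(ifft2c(y)))
  if (scale == 0) stop("all-zero k-space cannot be normalized")
  list(y = y / scale, scale = scale)
}

#' Z-score normalization over a whole sample
#'
#' Mean and standard deviation are computed jointly over all frames, pixels
#' and both real/imaginary channels of the sample; `zscore_unnorm()` inverts
#' the mapping exactly. A standard deviation below `eps` is clamped, so a
#' constant input maps to zero.
#'
#' @param x numeric or complex array.
#' @param eps clamp for the standard deviation (default `1e-8`).
#' @return `zscore_norm`: list `(x, mean, sd)`; `zscore_unnorm`: the restored
#'   array.
#' @export
zscore_norm <- function(x, eps = 1e-8) {
  v <- if (is.complex(x)) c(Re(x), Im(x)) else as.numeric(x)
  m <- mean(v)
  s <- stats::sd(v)
  if (!is.finite(s) || s < eps) s <- eps
  # complex arrays are treated as their two-channel view: the scalar mean is
  # removed from the real and imaginary channels alike
  mm <- if (is.complex(x)) complex(real = m, imaginary = m) else m
  list(x = (x - mm) / s, mean = mm, sd = s)
}

#' @rdname zscore_norm
#' @param m,s the moments returned by `zscore_norm`.
#' @export
zscore_unnorm <- function(x, m, s) x * s + m
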