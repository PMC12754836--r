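# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's compiled kernels and vectorized code paths: plain
# nested loops only.

# direct "same"-padding 2D convolution of an (H, W, Cin, T) array with an
# (kh, kw, Cin, Cout) kernel; matches the layout of the compiled kernel
brute_conv2d <- function(x, w, b = NULL, stride = 1L, dilation = 1L) {
  d <- dim(x); wd <- dim(w)
  H <- d[1]; W <- d[2]; Cin <- d[3]; T_ <- d[4]
  kh <- wd[1]; kw <- wd[2]; Cout <- wd[4]
  p <- dilation * (kh - 1) %/% 2
  Ho <- (H + 2 * p - dilation * (kh - 1) - 1) %/% stride + 1
  Wo <- (W + 2 * p - dilation * (kw - 1) - 1) %/% stride + 1
  if (is.null(b)) b <- numeric(Cout)
  out <- array(0, c(Ho, Wo, Cout, T_))
  for (t in seq_len(T_)) for (o in seq_len(Cout)) {
    acc <- matrix(b[o], Ho, Wo)
    for (ci in seq_len(Cin)) for (ih in seq_len(kh)) for (iw in seq_len(kw)) {
      for (ho in seq_len(Ho)) for (wo in seq_len(Wo)) {
        hi <- (ho - 1) * stride - p + (ih - 1) * dilation + 1
        wi <- (wo - 1) * stride - p + (iw - 1) * dilation + 1
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
          acc[ho, wo] <- acc[ho, wo] + x[hi, wi, ci, t] * w[ih, iw, ci, o]
      }
    }
    out[, , o, t] <- acc
  }
  out
}

# frame-by-frame recurrence oracle for the convolutional recurrent unit:
# H_t = relu(W_l * x_t + W_t * H_prev + W_i * prev_cascade_t + B)
brute_crnn <- function(x, prev, w_l, w_t, w_i, b, direction) {
  T_ <- dim(x)[4]
  ord <- if (direction == "forward") seq_len(T_) else rev(seq_len(T_))
  hidden <- NULL
  out <- array(0, c(dim(x)[1:2], dim(w_l)[4], T_))
  for (t in ord) {
    a <- brute_conv2d(x[, , , t, drop = FALSE], w_l, b)
    if (!is.null(prev) && !is.null(w_i))
      a <- a + brute_conv2d(prev[, , , t, drop = FALSE], w_i)
    if (!is.null(hidden))
      a <- a + brute_conv2d(hidden, w_t)
    hidden <- pmax(a, 0)
    out[, , , t] <- hidden
  }
  out
}

# per-index evaluation of the data-consistency blend: for every k-space
# index, keep the transform of z off the acquired set and blend/replace on
# it, then return the coil-combined image
brute_dc <- function(z, y, S, mask, lambda0 = Inf) {
  kz <- fft2c(coil_expand(z, S))
  d <- dim(kz)
  acq <- mask$acquired_rows + 1L
  out_k <- array(0i, d)
  for (t in seq_len(d[1])) for (c in seq_len(d[2]))
    for (r in seq_len(d[3])) for (w in seq_len(d[4])) {
      if (r %in% acq) {
        out_k[t, c, r, w] <- if (is.infinite(lambda0)) y[t, c, r, w] else
          (kz[t, c, r, w] + lambda0 * y[t, c, r, w]) / (1 + lambda0)
      } else out_k[t, c, r, w] <- kz[t, c, r, w]
    }
  list(image = coil_combine(ifft2c(out_k), S), kspace = out_k)
}

# direct windowed local-SSIM evaluation: loops over pixels, gathering the
# Gaussian-weighted window statistics with zero padding outside the image
brute_ssim <- function(a, b, data_range, size = 11L, sigma = 1.5) {
  r <- seq_len(size) - (size + 1) / 2
  g <- exp(-r^2 / (2 * sigma^2))
  win <- outer(g, g); win <- win / sum(win)
  c1 <- (0.01 * data_range)^2; c2 <- (0.03 * data_range)^2
  H <- nrow(a); W <- ncol(a); half <- (size - 1) %/% 2
  vals <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    mua <- mub <- saa <- sbb <- sab <- 0
    for (di in -half:half) for (dj in -half:half) {
      ii <- i + di; jj <- j + dj
      av <- if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) a[ii, jj] else 0
      bv <- if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) b[ii, jj] else 0
      wgt <- win[di + half + 1, dj + half + 1]
      mua <- mua + wgt * av; mub <- mub + wgt * bv
      saa <- saa + wgt * av^2; sbb <- sbb + wgt * bv^2; sab <- sab + wgt * av * bv
    }
    saa <- saa - mua^2; sbb <- sbb - mub^2; sab <- sab - mua * mub
    vals[i, j] <- ((2 * mua * mub + c1) * (2 * sab + c2)) /
                  ((mua^2 + mub^2 + c1) * (saa + sbb + c2))
  }
  mean(vals)
}

# restrict a (T,C,H,W) k-space to the acquired rows of a mask
apply_mask_for_test <- function(y, mask) {
  out <- array(0i, dim(y))
  keep <- mask$acquired_rows + 1L
  out[, , keep, ] <- y[, , keep, ]
  out
}

# small random complex array helper
rcplx <- function(dims) {
  array(complex(real = rnorm(prod(dims)), imaginary = rnorm(prod(dims))), dims)
}

# compact multi-coil toy scene: phantom image, unit-SOS maps, mask
toy_scene <- function(T = 3L, H = 12L, W = 12L, C = 3L, accel = 3L,
                      acs = 2L, seed = 11L) {
  sp <- phantom_spec(T = T, H = H, W = W, n_coils = C, seed = seed)
  list(spec = sp, x = make_phantom(sp)$img, S = make_coil_maps(sp),
       mask = make_mask(H, W, accel, acs_lines = acs))
}

# finite-difference gradient comparison for tape subgraphs
fd_gradcheck <- function(make_loss, params, n_idx = 5L, eps = 1e-6) {
  ns <- asNamespace("cinerecon")
  for (p in params) p$grad <- NULL
  ns$ad_tape_begin()
  loss <- make_loss()
  ns$ad_backward(loss)
  ns$ad_tape_end()
  ana <- lapply(params, function(p) if (is.null(p$grad)) 0 * p$value else p$grad)
  worst <- 0
  for (i in seq_along(params)) {
    p <- params[[i]]
    for (j in sample(length(p$value), min(n_idx, length(p$value)))) {
      v0 <- p$value[j]
      p$value[j] <- v0 + eps; lp <- make_loss()$value
      p$value[j] <- v0 - eps; lm <- make_loss()$value
      p$value[j] <- v0
      num <- (lp - lm) / (2 * eps)
      worst <- max(worst, abs(num - ana[[i]][j]) /
                            max(1e-7, abs(num), abs(ana[[i]][j])))
    }
  }
  worst
}
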