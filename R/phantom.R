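#' Specification of the synthetic beating-heart cine phantom
#'
#' The generator emulates the statistical structure of a retrospectively
#' gated multi-coil cine acquisition: a cyclic sequence of `T` frames
#' (frame `T+1` equals frame 1 exactly, so the temporal circular-padding
#' assumption holds by construction), strong inter-frame correlation, a
#' single fixed undersampling mask across frames, and smooth complex coil
#' sensitivity profiles. The scene is a background ellipse (torso), a set of
#' static elliptical structures, and a "myocardial" annulus whose inner and
#' outer radii oscillate sinusoidally over the cycle around a bright blood
#' pool.
#'
#' @param T number of frames (default 12, one cardiac cycle).
#' @param H,W spatial size (default 64 x 64).
#' @param n_coils number of receiver coils (default 8).
#' @param motion_amplitude fractional radius modulation of the annulus over
#'   the cycle (default 0.15).
#' @param n_static_structures number of random static ellipses (default 4).
#' @param noise_sigma standard deviation of the complex Gaussian k-space
#'   noise added by [simulate_acquisition()] (default 0, set per call).
#' @param seed integer seed; the phantom is a deterministic function of the
#'   spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(T = 12L, H = 64L, W = 64L, n_coils = 8L,
                         motion_amplitude = 0.15, n_static_structures = 4L,
                         noise_sigma = 0, seed = 1L) {
  stopifnot(T >= 2, H >= 4, W >= 4, n_coils >= 1,
            motion_amplitude >= 0, motion_amplitude < 1, noise_sigma >= 0)
  structure(list(T = as.integer(T), H = as.integer(H), W = as.integer(W),
                 n_coils = as.integer(n_coils),
                 motion_amplitude = motion_amplitude,
                 n_static_structures = as.integer(n_static_structures),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# smooth indicator of an ellipse via a sigmoid of the signed "radius"
.soft_ellipse <- function(X, Y, cx, cy, rx, ry, softness = 1.5) {
  r <- sqrt(((X - cx) / rx)^2 + ((Y - cy) / ry)^2)
  1 / (1 + exp((r - 1) * rx / softness))
}

#' Generate the beating-heart phantom
#'
#' Returns the complex ground-truth image sequence and the union of the
#' moving annulus' per-frame supports (the known moving region, against
#' which the temporal-standard-deviation dynamic mask can be validated).
#' The annulus radii vary as `r(t) = r0 * (1 + a * sin(2*pi*(t-1)/T))`, so
#' the motion has period exactly `T`. A smooth low-order polynomial phase
#' makes the object genuinely complex; magnitudes are scaled to unit
#' maximum.
#'
#' @param spec a [phantom_spec()].
#' @return list with `img` (complex `(T, H, W)`), `moving_support` (logical
#'   `(H, W)`), and the generating `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  H <- spec$H; W <- spec$W; T_ <- spec$T
  X <- matrix(seq(-1, 1, length.out = H), H, W)
  Y <- matrix(seq(-1, 1, length.out = W), H, W, byrow = TRUE)

  torso <- 0.45 * .soft_ellipse(X, Y, 0, 0, 0.92, 0.95)
  static <- torso
  for (i in seq_len(spec$n_static_structures)) {
    cx <- stats::runif(1, -0.55, 0.55); cy <- stats::runif(1, -0.55, 0.55)
    rx <- stats::runif(1, 0.08, 0.22); ry <- stats::runif(1, 0.08, 0.22)
    amp <- stats::runif(1, -0.2, 0.3)
    static <- static + amp * .soft_ellipse(X, Y, cx, cy, rx, ry)
  }

  # heart: annulus centered slightly off-axis
  cx <- stats::runif(1, -0.15, 0.05); cy <- stats::runif(1, -0.1, 0.1)
  r_in0 <- stats::runif(1, 0.14, 0.18)
  r_out0 <- r_in0 + stats::runif(1, 0.1, 0.14)
  a <- spec$motion_amplitude
  if (r_out0 * (1 + a) >= 0.95) stop("annulus radii exceed the field of view")

  # smooth spatial phase (low-order polynomial)
  ph <- stats::runif(4, -1, 1)
  phase <- exp(1i * (ph[1] + ph[2] * X + ph[3] * Y + ph[4] * X * Y))

  img <- array(0i, c(T_, H, W))
  moving <- matrix(FALSE, H, W)
  rr <- sqrt((X - cx)^2 + (Y - cy)^2)
  for (t in seq_len(T_)) {
    s <- 1 + a * sin(2 * pi * (t - 1) / T_)
    r_in <- r_in0 * s; r_out <- r_out0 * s
    annulus <- .soft_ellipse(X, Y, cx, cy, r_out, r_out) -
               .soft_ellipse(X, Y, cx, cy, r_in, r_in)
    pool <- .soft_ellipse(X, Y, cx, cy, r_in, r_in)
    frame <- static + 0.55 * annulus + 0.35 * pool
    img[t, , ] <- frame * phase
    moving <- moving | (rr >= r_in0 * (1 - a) * 0.9 & rr <= r_out0 * (1 + a) * 1.1)
  }
  img <- img / max(Mod(img))
  list(img = img, moving_support = moving, spec = spec)
}

#' Smooth complex coil sensitivity maps
#'
#' `n_coils` Gaussian-magnitude profiles centered at equidistant angles
#' around the field of view, each with a smooth linear phase, normalized
#' pixelwise to unit sum of squares so that conjugate coil combination
#' after expansion is the identity.
#'
#' @param spec a [phantom_spec()].
#' @return complex array `(C, H, W)` with pixelwise unit sum of squares.
#' @export
make_coil_maps <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$H; W <- spec$W; C <- spec$n_coils
  X <- matrix(seq(-1, 1, length.out = H), H, W)
  Y <- matrix(seq(-1, 1, length.out = W), H, W, byrow = TRUE)
  S <- array(0i, c(C, H, W))
  for (c in seq_len(C)) {
    th <- 2 * pi * (c - 1) / C
    cx <- 0.9 * cos(th); cy <- 0.9 * sin(th)
    mag <- exp(-((X - cx)^2 + (Y - cy)^2) / (2 * 0.7^2))
    phs <- exp(1i * (0.5 * cos(th) * X + 0.5 * sin(th) * Y))
    S[c, , ] <- mag * phs
  }
  normalize_coil_maps(S)
}

#' Simulate a multi-coil cine acquisition
#'
#' Applies the coil model and centered FFT to the ground truth, adds
#' complex Gaussian noise of standard deviation `noise_sigma` to the fully
#' sampled k-space, and zeroes the unacquired rows to form the undersampled
#' copy. Noise is added before masking, so the fully sampled and
#' undersampled data share the same realization.
#'
#' @param x complex ground-truth sequence `(T, H, W)`.
#' @param S coil maps `(C, H, W)`.
#' @param mask a [make_mask()] object or pattern matrix.
#' @param noise_sigma k-space complex-noise standard deviation.
#' @param seed seed for the noise realization.
#' @return list with `y` (undersampled k-space `(T, C, H, W)`) and
#'   `y_full` (fully sampled k-space).
#' @export
simulate_acquisition <- function(x, S, mask, noise_sigma = 0, seed = 1L) {
  mask <- as_sampling_mask(mask)
  y_full <- fft2c(coil_expand(x, S))
  if (noise_sigma > 0) {
    old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    n <- length(y_full)
    y_full <- y_full + complex(real = stats::rnorm(n, 0, noise_sigma),
                               imaginary = stats::rnorm(n, 0, noise_sigma))
  }
  list(y = apply_mask(y_full, mask), y_full = y_full)
}

#' Write a dataset of simulated slices
#'
#' Generates `n_slices` independent phantom slices (per-slice seeds derived
#' deterministically from the master seed in the spec), simulates their
#' acquisitions under one mask specification, writes one slice container
#' per slice via [write_slice()], and a `manifest.csv` listing files and
#' seeds.
#'
#' @param n_slices number of slices.
#' @param spec a [phantom_spec()]; its `seed` acts as the master seed.
#' @param mask a [make_mask()] object applied to every slice.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
make_dataset <- function(n_slices, spec, mask, out_dir) {
  stopifnot(inherits(spec, "phantom_spec"))
  mask <- as_sampling_mask(mask)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(n_slices); seeds <- integer(n_slices)
  for (i in seq_len(n_slices)) {
    s <- as.integer((as.numeric(spec$seed) * 10007 + i * 7919) %% 2147483647)
    sspec <- spec; sspec$seed <- as.integer(s)
    ph <- make_phantom(sspec)
    S <- make_coil_maps(sspec)
    acq <- simulate_acquisition(ph$img, S, mask, sspec$noise_sigma, seed = s + 1L)
    f <- file.path(out_dir, sprintf("slice_%03d.rds", i))
    write_slice(f, kspace = acq$y, sensitivity = S, mask = mask,
                ground_truth = ph$img,
                attrs = list(nominal_R = mask$accel, acs_lines = mask$acs_lines,
                             seed = s, moving_support = ph$moving_support))
    files[i] <- basename(f); seeds[i] <- s
  }
  manifest <- data.frame(file = files, seed = seeds,
                         T = spec$T, H = spec$H, W = spec$W,
                         n_coils = spec$n_coils,
                         noise_sigma = spec$noise_sigma)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
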