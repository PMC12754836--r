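#' Reconstruction quality metrics
#'
#' `psnr()` computes the peak signal-to-noise ratio
#' `10 * log10(data_range^2 / MSE)` over all frames and pixels of the
#' magnitude sequences; `ssim_eval()` the frame-averaged structural
#' similarity of the magnitude sequences. Complex inputs are reduced to
#' magnitudes first; the default data range is the maximum ground-truth
#' magnitude.
#'
#' @param rec,gnd reconstruction and reference: `(T, H, W)` arrays (complex
#'   or magnitude) or matrices.
#' @param data_range positive scalar; default `max(Mod(gnd))`.
#' @param cap PSNR value reported when the MSE is zero (default 100 dB).
#' @return scalar (dB for `psnr`).
#' @export
psnr <- function(rec, gnd, data_range = NULL, cap = 100) {
  rec <- .as_mag(rec); gnd <- .as_mag(gnd)
  if (!identical(dim(rec), dim(gnd))) stop("shape mismatch")
  if (is.null(data_range)) data_range <- max(gnd)
  if (data_range <= 0) stop("data_range must be positive")
  mse <- mean((rec - gnd)^2)
  if (mse == 0) return(cap)
  min(10 * log10(data_range^2 / mse), cap)
}

#' @rdname psnr
#' @export
ssim_eval <- function(rec, gnd, data_range = NULL) {
  rec <- .as_mag(rec); gnd <- .as_mag(gnd)
  if (is.null(data_range)) data_range <- max(gnd)
  ssim_index(rec, gnd, data_range)
}

.as_mag <- function(x) if (is.complex(x)) Mod(x) else x

#' Dynamic-region mask from the temporal standard deviation
#'
#' Moving tissue changes intensity rapidly across the cine sequence, so the
#' per-pixel standard deviation of the ground-truth magnitude along the
#' temporal axis is high there. Pixels whose temporal standard deviation
#' strictly exceeds the given percentile of all pixels' values form the
#' dynamic region; the remainder is the static region.
#'
#' @param gnd ground-truth sequence `(T, H, W)`, complex or magnitude,
#'   with at least 2 frames.
#' @param percentile percentile threshold in `[0, 100)` (default 90).
#' @return an object of class `region_mask`: list with the logical
#'   `dynamic` matrix `(H, W)`, the `threshold`, the `percentile` and the
#'   temporal standard-deviation map `std`.
#' @export
dynamic_mask <- function(gnd, percentile = 90) {
  m <- .as_mag(gnd)
  if (length(dim(m)) != 3 || dim(m)[1] < 2)
    stop("need a (T, H, W) sequence with at least 2 frames")
  std <- apply(m, c(2, 3), stats::sd)
  thr <- stats::quantile(std, percentile / 100, names = FALSE)
  structure(list(dynamic = std > thr, threshold = thr,
                 percentile = percentile, std = std),
            class = "region_mask")
}

#' Region-restricted PSNR and SSIM
#'
#' Splits the image into the dynamic region and its complement (the static
#' region) and evaluates each separately: PSNR from the mean squared error
#' restricted to the region's pixels across all frames, and SSIM as the
#' mean of the full-image local SSIM map over the region's pixels (windows
#' near region boundaries therefore also see out-of-region pixels; SSIM is
#' not defined on bare point sets).
#'
#' @param rec,gnd sequences `(T, H, W)`, complex or magnitude.
#' @param mask a [dynamic_mask()] object or a logical `(H, W)` matrix
#'   marking the dynamic region.
#' @param data_range default `max(Mod(gnd))`.
#' @param cap PSNR cap for zero region error.
#' @return list with elements `dynamic` and `static`, each `c(psnr, ssim)`,
#'   plus `n_dynamic`. Empty regions yield `NA` entries.
#' @export
region_metrics <- function(rec, gnd, mask, data_range = NULL, cap = 100) {
  rec <- .as_mag(rec); gnd <- .as_mag(gnd)
  if (!identical(dim(rec), dim(gnd))) stop("shape mismatch")
  dyn <- if (inherits(mask, "region_mask")) mask$dynamic else mask
  if (!identical(dim(dyn), dim(gnd)[2:3])) stop("mask shape mismatch")
  if (is.null(data_range)) data_range <- max(gnd)
  smap <- ssim_map(rec, gnd, data_range)   # (T, H, W)
  one_region <- function(sel) {
    if (!any(sel)) return(c(psnr = NA_real_, ssim = NA_real_))
    se <- 0; n <- 0; sv <- 0
    T_ <- dim(rec)[1]
    for (t in seq_len(T_)) {
      d2 <- (rec[t, , ] - gnd[t, , ])^2
      se <- se + sum(d2[sel]); n <- n + sum(sel)
      sv <- sv + mean(smap[t, , ][sel])
    }
    mse <- se / n
    p <- if (mse == 0) cap else min(10 * log10(data_range^2 / mse), cap)
    c(psnr = p, ssim = sv / T_)
  }
  list(dynamic = one_region(dyn), static = one_region(!dyn),
       n_dynamic = sum(dyn))
}
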