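#' Uniform Cartesian undersampling masks with a central ACS block
#'
#' Builds the line-sampling pattern used for accelerated cine acquisitions:
#' every `accel`-th phase-encode row (starting at `offset`, rows indexed from
#' 0) plus a fully sampled block of `acs_lines` contiguous central rows, the
#' auto-calibration signal (ACS). The readout (column) axis is always fully
#' sampled, so the pattern is constant along columns, and the same mask is
#' applied to every frame of the sequence.
#'
#' For even `n_rows` the ACS block covers rows
#' `n_rows/2 - acs_lines/2` to `n_rows/2 + acs_lines/2 - 1`; for odd sizes it
#' starts at `floor(n_rows/2) - floor(acs_lines/2)`.
#'
#' Note the distinction between the nominal acceleration `accel` and the
#' effective acceleration reported by [effective_acceleration()]: the ACS
#' block adds extra acquired lines, e.g. 192 rows at nominal R = 4 with a
#' 24-line ACS yields 66 acquired rows, an effective acceleration of
#' 192/66 (about 2.9).
#'
#' @param n_rows,n_cols mask size; rows are the phase-encode (undersampled)
#'   direction.
#' @param accel nominal acceleration factor (integer >= 1).
#' @param acs_lines number of fully sampled central rows (default 24).
#' @param offset shift of the uniform sampling comb, in `[0, accel)`.
#' @return an object of class `sampling_mask`: a list with the binary
#'   `pattern` matrix (`n_rows` x `n_cols`), sorted 0-based `acquired_rows`
#'   and `acs_rows`, and the generating parameters.
#' @examples
#' m <- make_mask(192, 144, accel = 4, acs_lines = 24)
#' length(m$acquired_rows)       # 66
#' effective_acceleration(m)     # 192/66
#' @export
make_mask <- function(n_rows, n_cols, accel, acs_lines = 24L, offset = 0L) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  accel <- as.integer(accel); acs_lines <- as.integer(acs_lines)
  offset <- as.integer(offset)
  if (accel < 1L) stop("nominal acceleration must be >= 1")
  if (acs_lines < 0L || acs_lines > n_rows)
    stop("acs_lines must lie in [0, n_rows]")
  if (offset < 0L || offset >= accel) stop("offset must lie in [0, accel)")
  rows <- seq.int(0L, n_rows - 1L)
  uniform <- rows[rows %% accel == offset]
  if (acs_lines > 0L) {
    start <- n_rows %/% 2L - acs_lines %/% 2L
    acs <- seq.int(start, start + acs_lines - 1L)
  } else acs <- integer(0)
  acquired <- sort(unique(c(uniform, acs)))
  if (length(acquired) == 0L) stop("mask acquires no rows")
  pattern <- matrix(0L, n_rows, n_cols)
  pattern[acquired + 1L, ] <- 1L
  structure(
    list(pattern = pattern, acquired_rows = acquired, acs_rows = acs,
         n_rows = n_rows, n_cols = n_cols, accel = accel,
         acs_lines = acs_lines, offset = offset),
    class = "sampling_mask")
}

#' Effective acceleration of a sampling mask
#'
#' Total phase-encode rows divided by the number actually acquired (uniform
#' comb plus ACS block). Always at most the nominal factor, because the ACS
#' lines are extra.
#'
#' @param mask a [make_mask()] object (or a binary pattern matrix whose rows
#'   are phase-encode lines).
#' @return a positive scalar.
#' @export
effective_acceleration <- function(mask) {
  mask <- as_sampling_mask(mask)
  n_acq <- length(mask$acquired_rows)
  if (n_acq == 0L) stop("mask acquires no rows")
  mask$n_rows / n_acq
}

#' Coerce a binary pattern matrix to a `sampling_mask`
#'
#' @param x a `sampling_mask` or a binary matrix constant along columns.
#' @return a `sampling_mask`.
#' @export
as_sampling_mask <- function(x) {
  if (inherits(x, "sampling_mask")) return(x)
  if (!is.matrix(x)) stop("expected a sampling_mask or a binary matrix")
  acquired <- which(rowSums(x != 0) > 0) - 1L
  if (any(x[acquired + 1L, ] == 0))
    stop("mask pattern must be constant along the column (readout) axis")
  structure(
    list(pattern = (x != 0) + 0L, acquired_rows = acquired,
         acs_rows = integer(0), n_rows = nrow(x), n_cols = ncol(x),
         accel = NA_integer_, acs_lines = NA_integer_, offset = NA_integer_),
    class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("sampling_mask: %d x %d, nominal R = %s, ACS lines = %s\n",
              x$n_rows, x$n_cols,
              ifelse(is.na(x$accel), "?", x$accel),
              ifelse(is.na(x$acs_lines), "?", x$acs_lines)))
  cat(sprintf("  acquired rows: %d (effective acceleration %.3f)\n",
              length(x$acquired_rows), effective_acceleration(x)))
  invisible(x)
}
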