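#' Centered orthonormal 2D Fourier transforms
#'
#' `fft2c()` and `ifft2c()` apply the centered ("shifted") orthonormal 2D
#' discrete Fourier transform over the last two axes of an array, the
#' convention under which the DC component sits at the array center and the
#' transform preserves energy (Parseval). The image axes are the trailing
#' `(row, column)` pair; any leading frame/coil axes are mapped over.
#'
#' MRI acquires data in the spatial-frequency domain (k-space); these two
#' transforms move between k-space and image space. The orthonormal scaling
#' (`1/sqrt(H*W)` both ways) keeps loss magnitudes comparable across matrix
#' sizes and makes the operator pair exactly unitary: `ifft2c(fft2c(x))`
#' reproduces `x` to machine precision and `||fft2c(x)|| == ||x||`.
#'
#' @param x complex (or numeric) array of rank 2-4; the last two axes are
#'   spatial (rows, columns).
#' @return array of the same shape and type `complex`.
#' @examples
#' img <- array(0i, c(8, 8)); img[5, 5] <- 1   # centered impulse
#' range(Mod(fft2c(img)))                      # flat spectrum, 1/8
#' @export
fft2c <- function(x) {
  .fft2c_apply(x, inverse = FALSE)
}

#' @rdname fft2c
#' @export
ifft2c <- function(x) {
  .fft2c_apply(x, inverse = TRUE)
}

.fft2c_apply <- function(x, inverse) {
  if (is.null(dim(x))) stop("input must be an array with at least 2 dimensions")
  if (!all(is.finite(Re(x))) || (is.complex(x) && !all(is.finite(Im(x)))))
    stop("non-finite values in Fourier transform input")
  f <- function(m) {
    hw <- dim(m)
    # both directions are the same ifftshift / transform / fftshift
    # sandwich; the order matters for odd axis lengths
    fftshift2(stats::fft(ifftshift2(m), inverse = inverse)) / sqrt(prod(hw))
  }
  map_spatial(x, f)
}

#' Shift the zero-frequency component to/from the array center
#'
#' `fftshift2` moves the `[1, 1]` (zero-frequency) element of a matrix to the
#' center; `ifftshift2` is its inverse. The two differ only for odd axis
#' lengths.
#'
#' @param m matrix (complex or numeric).
#' @return matrix of the same shape.
#' @export
fftshift2 <- function(m) {
  d <- dim(m)
  m[.roll_idx(d[1], d[1] %/% 2), .roll_idx(d[2], d[2] %/% 2), drop = FALSE]
}

#' @rdname fftshift2
#' @export
ifftshift2 <- function(m) {
  d <- dim(m)
  m[.roll_idx(d[1], -(d[1] %/% 2)), .roll_idx(d[2], -(d[2] %/% 2)), drop = FALSE]
}

# index permutation that rolls a length-n axis by k (as in a circular shift
# of the data by +k)
.roll_idx <- function(n, k) {
  ((seq_len(n) - 1 - k) %% n) + 1
}

# apply f(matrix) over the trailing two axes of a rank 2-4 array
map_spatial <- function(x, f) {
  d <- dim(x)
  r <- length(d)
  if (r == 2) return(f(x))
  out <- array(0i, d)
  if (r == 3) {
    for (i in seq_len(d[1])) out[i, , ] <- f(array(x[i, , ], d[2:3]))
  } else if (r == 4) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      out[i, j, , ] <- f(array(x[i, j, , ], d[3:4]))
  } else stop("arrays of rank ", r, " are not supported")
  out
}
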