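#' SENSE coil model: expand, combine, and normalize sensitivity maps
#'
#' A multi-coil acquisition observes the object through complex coil
#' sensitivity profiles `S`. `coil_expand()` multiplies a single-channel
#' complex image sequence by each coil profile; `coil_combine()` is its
#' adjoint, multiplying each coil image by the conjugated profile and
#' summing over coils. When the maps have unit sum-of-squares pixelwise
#' (`normalize_coil_maps()`), combine after expand is the identity.
#'
#' @param x complex image sequence, array `(T, H, W)`.
#' @param S coil sensitivity maps, complex array `(C, H, W)`, static across
#'   frames.
#' @return `coil_expand`: per-coil images `(T, C, H, W)`;
#'   `coil_combine`: a `(T, H, W)` image sequence.
#' @export
coil_expand <- function(x, S) {
  dx <- dim(x); dS <- dim(S)
  if (length(dx) != 3 || length(dS) != 3)
    stop("expected image (T,H,W) and maps (C,H,W)")
  if (!all(dx[2:3] == dS[2:3])) stop("spatial shape mismatch between image and maps")
  T_ <- dx[1]; C <- dS[1]
  out <- array(0i, c(T_, C, dx[2], dx[3]))
  for (t in seq_len(T_)) for (c in seq_len(C))
    out[t, c, , ] <- S[c, , ] * x[t, , ]
  out
}

#' @rdname coil_expand
#' @param coil_imgs per-coil complex image stack `(T, C, H, W)`.
#' @export
coil_combine <- function(coil_imgs, S) {
  dc <- dim(coil_imgs); dS <- dim(S)
  if (length(dc) != 4) stop("expected coil image stack (T,C,H,W)")
  if (dc[2] != dS[1] || !all(dc[3:4] == dS[2:3]))
    stop("coil/spatial shape mismatch between images and maps")
  out <- array(0i, dc[c(1, 3, 4)])
  for (t in seq_len(dc[1])) {
    acc <- array(0i, dc[3:4])
    for (c in seq_len(dc[2]))
      acc <- acc + Conj(S[c, , ]) * coil_imgs[t, c, , ]
    out[t, , ] <- acc
  }
  out
}

#' @rdname coil_expand
#' @param tol pixels whose sum-of-squares magnitude falls below `tol` are
#'   treated as outside the object support and left at zero.
#' @export
normalize_coil_maps <- function(S, tol = 1e-12) {
  sos <- sqrt(apply(Mod(S)^2, c(2, 3), sum))
  C <- dim(S)[1]
  out <- S
  scale <- ifelse(sos > tol, 1 / sos, 0)
  for (c in seq_len(C)) out[c, , ] <- S[c, , ] * scale
  out
}
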