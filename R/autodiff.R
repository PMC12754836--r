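# Reverse-mode automatic differentiation over dense array tensors.
#
# The engine is a flat tape: every operation appends a node (an environment
# holding the value, the parent references and a backward closure) to the
# active tape, and ad_backward() walks the tape in reverse creation order,
# which is a valid topological order because values are only consumed after
# they are produced. Network tensors use the (H, W, C, T) layout of the
# compiled convolution kernels. Trainable parameters live outside the tape
# as `ad_param` environments; gradients of all uses of a parameter within
# one forward pass are summed into its `grad` field.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

ad_tape_begin <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  .ad$tape <- t
  invisible(t)
}

ad_tape_end <- function() {
  .ad$tape <- NULL
  invisible(NULL)
}

ad_recording <- function() !is.null(.ad$tape)

ad_node <- function(value, backward = NULL, req = FALSE) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$backward <- backward
  n$req <- req
  n$sink <- NULL
  class(n) <- "ad_node"
  t <- .ad$tape
  if (!is.null(t) && req) {
    t$n <- t$n + 1L
    if (t$n > length(t$nodes)) t$nodes <- c(t$nodes, vector("list", length(t$nodes)))
    t$nodes[[t$n]] <- n
  }
  n
}

ad_const <- function(value) ad_node(value, req = FALSE)

#' @keywords internal
ad_param <- function(value, name = "") {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$name <- name
  class(p) <- "ad_param"
  p
}

# wrap a parameter as a tape node; backward adds into p$grad
ad_use <- function(p) {
  n <- ad_node(p$value, req = TRUE)
  n$sink <- p
  n
}

ad_accum <- function(node, g) {
  if (!node$req) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# seed the output node with gradient 1 and sweep the tape backwards
ad_backward <- function(loss) {
  t <- .ad$tape
  if (is.null(t)) stop("no active tape")
  loss$grad <- 1
  for (i in seq.int(t$n, 1L)) {
    nd <- t$nodes[[i]]
    if (!is.null(nd$grad)) {
      if (!is.null(nd$backward)) nd$backward(nd$grad)
      if (!is.null(nd$sink)) {
        p <- nd$sink
        p$grad <- if (is.null(p$grad)) nd$grad else p$grad + nd$grad
      }
    }
    nd$grad <- NULL
    t$nodes[i] <- list(NULL)
  }
  invisible(NULL)
}

.req <- function(...) any(vapply(list(...), function(n) isTRUE(n$req), logical(1)))

## ---- elementwise and structural ops -------------------------------------

op_add <- function(a, b) {
  ad_node(a$value + b$value, req = .req(a, b), backward = function(g) {
    ad_accum(a, g); ad_accum(b, g)
  })
}

op_sub <- function(a, b) {
  ad_node(a$value - b$value, req = .req(a, b), backward = function(g) {
    ad_accum(a, g); ad_accum(b, -g)
  })
}

op_mul <- function(a, b) {
  ad_node(a$value * b$value, req = .req(a, b), backward = function(g) {
    ad_accum(a, g * b$value); ad_accum(b, g * a$value)
  })
}

op_div <- function(a, b) {
  out <- a$value / b$value
  ad_node(out, req = .req(a, b), backward = function(g) {
    ad_accum(a, g / b$value)
    ad_accum(b, -g * out / b$value)
  })
}

op_scale <- function(x, k) {
  ad_node(x$value * k, req = x$req, backward = function(g) ad_accum(x, g * k))
}

op_addc <- function(x, k) {
  ad_node(x$value + k, req = x$req, backward = function(g) ad_accum(x, g))
}

op_relu <- function(x) {
  keep <- x$value > 0
  ad_node(x$value * keep, req = x$req,
          backward = function(g) ad_accum(x, g * keep))
}

op_abs <- function(x) {
  sg <- sign(x$value)
  ad_node(abs(x$value), req = x$req,
          backward = function(g) ad_accum(x, g * sg))
}

op_mean <- function(x) {
  n <- length(x$value)
  ad_node(mean(x$value), req = x$req,
          backward = function(g) ad_accum(x, array(g / n, dim(x$value))))
}

## ---- frame slicing / stacking -------------------------------------------

op_slice_t <- function(x, t) {
  d <- dim(x$value)
  v <- x$value[, , , t, drop = FALSE]
  ad_node(v, req = x$req, backward = function(g) {
    gx <- array(0, d)
    gx[, , , t] <- g
    ad_accum(x, gx)
  })
}

op_stack_t <- function(frames) {
  d1 <- dim(frames[[1]]$value)
  T_ <- length(frames)
  v <- array(0, c(d1[1:3], T_))
  for (t in seq_len(T_)) v[, , , t] <- frames[[t]]$value
  req <- any(vapply(frames, function(f) f$req, logical(1)))
  ad_node(v, req = req, backward = function(g) {
    for (t in seq_len(T_))
      ad_accum(frames[[t]], g[, , , t, drop = FALSE])
  })
}

# circular or zero-padded frame shift by k (frame t of the output is frame
# t - k of the input)
op_shift_time <- function(x, k, circular = TRUE) {
  d <- dim(x$value)
  T_ <- d[4]
  if (circular) {
    idx <- ((seq_len(T_) - 1 - k) %% T_) + 1
    v <- x$value[, , , idx, drop = FALSE]
    ad_node(v, req = x$req, backward = function(g) {
      back <- ((seq_len(T_) - 1 + k) %% T_) + 1
      ad_accum(x, g[, , , back, drop = FALSE])
    })
  } else {
    v <- array(0, d)
    src <- seq_len(T_) - k
    ok <- src >= 1 & src <= T_
    v[, , , which(ok)] <- x$value[, , , src[ok]]
    ad_node(v, req = x$req, backward = function(g) {
      gx <- array(0, d)
      gx[, , , src[ok]] <- g[, , , which(ok)]
      ad_accum(x, gx)
    })
  }
}

## ---- convolutions --------------------------------------------------------

op_conv2d <- function(x, w, b = NULL, stride = 1L, dilation = 1L) {
  Cout <- dim(w$value)[4]
  bv <- if (is.null(b)) numeric(Cout) else b$value
  out <- cpp_conv2d_fwd(x$value, w$value, bv, as.integer(stride),
                        as.integer(dilation))
  xd <- dim(x$value)
  ad_node(out, req = .req(x, w) || (!is.null(b) && b$req),
          backward = function(g) {
    if (x$req)
      ad_accum(x, cpp_conv2d_bwx(g, w$value, xd, as.integer(stride),
                                 as.integer(dilation)))
    if (w$req || (!is.null(b) && b$req)) {
      gr <- cpp_conv2d_bww(x$value, g, dim(w$value), as.integer(stride),
                           as.integer(dilation))
      ad_accum(w, gr$gw)
      if (!is.null(b)) ad_accum(b, gr$gb)
    }
  })
}

op_conv1d_time <- function(x, w, b = NULL, circular = TRUE) {
  Cout <- dim(w$value)[3]
  bv <- if (is.null(b)) numeric(Cout) else b$value
  out <- cpp_conv1d_time_fwd(x$value, w$value, bv, isTRUE(circular))
  ad_node(out, req = .req(x, w) || (!is.null(b) && b$req),
          backward = function(g) {
    gr <- cpp_conv1d_time_bw(x$value, g, w$value, isTRUE(circular))
    ad_accum(x, gr$gx)
    ad_accum(w, gr$gw)
    if (!is.null(b)) ad_accum(b, gr$gb)
  })
}

## ---- resampling ----------------------------------------------------------

# nearest-neighbour x2 upsampling of the spatial axes
op_upsample2 <- function(x) {
  d <- dim(x$value)
  ri <- rep(seq_len(d[1]), each = 2)
  ci <- rep(seq_len(d[2]), each = 2)
  v <- x$value[ri, ci, , , drop = FALSE]
  ad_node(v, req = x$req, backward = function(g) {
    # 2x2 block sums
    g1 <- g[seq(1, 2 * d[1], 2), , , , drop = FALSE] +
          g[seq(2, 2 * d[1], 2), , , , drop = FALSE]
    gx <- g1[, seq(1, 2 * d[2], 2), , , drop = FALSE] +
          g1[, seq(2, 2 * d[2], 2), , , drop = FALSE]
    ad_accum(x, gx)
  })
}

# zero-pad the spatial axes on the bottom/right to the target size
op_pad_hw <- function(x, H, W) {
  d <- dim(x$value)
  if (d[1] == H && d[2] == W) return(x)
  v <- array(0, c(H, W, d[3], d[4]))
  v[seq_len(d[1]), seq_len(d[2]), , ] <- x$value
  ad_node(v, req = x$req, backward = function(g) {
    ad_accum(x, g[seq_len(d[1]), seq_len(d[2]), , , drop = FALSE])
  })
}

op_crop_hw <- function(x, H, W) {
  d <- dim(x$value)
  if (d[1] == H && d[2] == W) return(x)
  v <- x$value[seq_len(H), seq_len(W), , , drop = FALSE]
  ad_node(v, req = x$req, backward = function(g) {
    gx <- array(0, d)
    gx[seq_len(H), seq_len(W), , ] <- g
    ad_accum(x, gx)
  })
}

op_slice_c <- function(x, ci) {
  d <- dim(x$value)
  v <- x$value[, , ci, , drop = FALSE]
  ad_node(v, req = x$req, backward = function(g) {
    gx <- array(0, d)
    gx[, , ci, ] <- g
    ad_accum(x, gx)
  })
}

op_concat_c <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  v <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  v[, , seq_len(da[3]), ] <- a$value
  v[, , da[3] + seq_len(db[3]), ] <- b$value
  ad_node(v, req = .req(a, b), backward = function(g) {
    ad_accum(a, g[, , seq_len(da[3]), , drop = FALSE])
    ad_accum(b, g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

## ---- normalization -------------------------------------------------------

# sample-wide z-score; the moments are treated as constants in the backward
# pass (they vary negligibly per step and keeping them constant makes the
# block an affine map around the data)
op_zscore <- function(x, eps = 1e-8) {
  m <- mean(x$value)
  s <- stats::sd(as.numeric(x$value))
  if (!is.finite(s) || s < eps) s <- eps
  node <- ad_node((x$value - m) / s, req = x$req,
                  backward = function(g) ad_accum(x, g / s))
  list(node = node, mean = m, sd = s)
}

op_zscore_un <- function(x, m, s) {
  ad_node(x$value * s + m, req = x$req,
          backward = function(g) ad_accum(x, g * s))
}

## ---- layout conversion between complex and two-channel views -------------

#' Convert between complex image sequences and the network's channel view
#'
#' The network consumes real tensors of layout `(H, W, 2, T)` whose two
#' channels hold the real and imaginary parts; the physics operators consume
#' complex `(T, H, W)` arrays. These helpers convert losslessly between the
#' two views.
#'
#' @param x complex array `(T, H, W)` (for `cplx_to_net`) or real array
#'   `(H, W, 2, T)` (for `net_to_cplx`).
#' @return the other representation.
#' @export
cplx_to_net <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[2], d[3], 2, d[1]))
  out[, , 1, ] <- aperm(Re(x), c(2, 3, 1))
  out[, , 2, ] <- aperm(Im(x), c(2, 3, 1))
  out
}

#' @rdname cplx_to_net
#' @export
net_to_cplx <- function(x) {
  d <- dim(x)
  z <- complex(real = as.numeric(x[, , 1, ]), imaginary = as.numeric(x[, , 2, ]))
  aperm(array(z, c(d[1], d[2], d[4])), c(3, 1, 2))
}

## ---- physics ops on the tape ---------------------------------------------

# centered orthonormal FFT of a two-channel tensor; unitary, so the
# backward pass is the inverse transform
op_fft2c_2ch <- function(x) {
  v <- cplx_to_net(fft2c(net_to_cplx(x$value)))
  ad_node(v, req = x$req, backward = function(g) {
    ad_accum(x, cplx_to_net(ifft2c(net_to_cplx(g))))
  })
}

# k-space data consistency on a two-channel tensor. The map is affine in z
# with a self-adjoint linear part (unitary FFT, adjoint coil pair, real
# diagonal blending weights), so the input gradient is the same masked
# blend applied to the output gradient with y = 0. In learnable mode the
# scalar log(lambda0) also receives a gradient.
op_dc <- function(z, y, S, mask, dc, log_lambda = NULL) {
  keep <- mask$acquired_rows + 1L
  learn <- !is.null(log_lambda) && dc$mode == "learnable"
  l0 <- if (dc$mode == "learnable") {
    exp(if (learn) log_lambda$value else dc$log_lambda0)
  } else Inf
  zc <- net_to_cplx(z$value)
  kz <- fft2c(coil_expand(zc, S))
  kz_keep <- kz[, , keep, , drop = FALSE]
  if (dc$mode == "hard") {
    kz[, , keep, ] <- y[, , keep, ]
  } else {
    kz[, , keep, ] <- (kz_keep + l0 * y[, , keep, , drop = FALSE]) / (1 + l0)
  }
  out <- cplx_to_net(coil_combine(ifft2c(kz), S))
  node <- ad_node(out, req = z$req || (learn && log_lambda$req), backward = function(g) {
    gk <- fft2c(coil_expand(net_to_cplx(g), S))
    if (learn) {
      diffk <- y[, , keep, , drop = FALSE] - kz_keep
      gl <- sum(Re(Conj(gk[, , keep, , drop = FALSE]) * diffk)) / (1 + l0)^2 * l0
      ad_accum(log_lambda, gl)
    }
    if (dc$mode == "hard") {
      gk[, , keep, ] <- 0
    } else {
      gk[, , keep, ] <- gk[, , keep, , drop = FALSE] / (1 + l0)
    }
    ad_accum(z, cplx_to_net(coil_combine(ifft2c(gk), S)))
  })
  node$kspace <- kz   # blended per-coil k-space: the reconstruction's y_rec
  node
}
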