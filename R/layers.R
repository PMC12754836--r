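# Building blocks of the recurrent U-Net: parameter constructors and
# tape-based forward functions. All tensors are (H, W, C, T).

# PyTorch-style uniform fan-in initialisation for a conv kernel
.init_kernel <- function(kh, kw, cin, cout) {
  bound <- 1 / sqrt(kh * kw * cin)
  array(stats::runif(kh * kw * cin * cout, -bound, bound), c(kh, kw, cin, cout))
}

.init_tkernel <- function(kt, cin, cout) {
  bound <- 1 / sqrt(kt * cin)
  array(stats::runif(kt * cin * cout, -bound, bound), c(kt, cin, cout))
}

new_conv2d <- function(k, cin, cout, name) {
  list(w = ad_param(.init_kernel(k, k, cin, cout), paste0(name, ".w")),
       b = ad_param(numeric(cout), paste0(name, ".b")))
}

new_conv1d <- function(kt, cin, cout, name) {
  list(w = ad_param(.init_tkernel(kt, cin, cout), paste0(name, ".w")),
       b = ad_param(numeric(cout), paste0(name, ".b")))
}

# factorized spatio-temporal Conv(2+1)D: per-frame 2D convolution followed
# by a temporal 1D convolution across frames
new_conv2p1d <- function(k, kt, cin, cout, name) {
  list(spatial = new_conv2d(k, cin, cout, paste0(name, ".spatial")),
       temporal = new_conv1d(kt, cout, cout, paste0(name, ".temporal")))
}

conv2p1d_forward <- function(x, pars, stride = 1L, dilation = 1L,
                             circular = TRUE, activation = TRUE) {
  h <- op_conv2d(x, ad_use(pars$spatial$w), ad_use(pars$spatial$b),
                 stride = stride, dilation = dilation)
  h <- op_conv1d_time(h, ad_use(pars$temporal$w), ad_use(pars$temporal$b),
                      circular = circular)
  if (activation) h <- op_relu(h) else h
}

# convolutional recurrent unit evolving over time and cascade index.
# W_l convolves the input from the previous layer, W_t the hidden state of
# the neighbouring frame, W_i the same layer's feature map from the
# previous cascade; the bias sits inside the activation.
new_crnn_ti <- function(k, cin, chid, cross, name) {
  p <- list(w_l = ad_param(.init_kernel(k, k, cin, chid), paste0(name, ".w_l")),
            w_t = ad_param(.init_kernel(k, k, chid, chid), paste0(name, ".w_t")),
            b = ad_param(numeric(chid), paste0(name, ".b")))
  if (cross)
    p$w_i <- ad_param(.init_kernel(k, k, chid, chid), paste0(name, ".w_i"))
  p
}

#' @keywords internal
crnn_ti_forward <- function(x, prev, pars, direction = c("forward", "backward"),
                            dilation = 1L) {
  direction <- match.arg(direction)
  T_ <- dim(x$value)[4]
  pre <- op_conv2d(x, ad_use(pars$w_l), ad_use(pars$b), dilation = dilation)
  if (!is.null(prev) && !is.null(pars$w_i)) {
    pre <- op_add(pre, op_conv2d(prev, ad_use(pars$w_i), NULL,
                                 dilation = dilation))
  }
  order <- if (direction == "forward") seq_len(T_) else rev(seq_len(T_))
  w_t <- ad_use(pars$w_t)
  hidden <- NULL
  out <- vector("list", T_)
  for (t in order) {
    a <- op_slice_t(pre, t)
    if (!is.null(hidden))
      a <- op_add(a, op_conv2d(hidden, w_t, NULL, dilation = dilation))
    hidden <- op_relu(a)
    out[[t]] <- hidden
  }
  op_stack_t(out)
}

#' @keywords internal
bcrnn_ti_forward <- function(x, prev, pars_fwd, pars_bwd, dilation = 1L) {
  op_add(crnn_ti_forward(x, prev, pars_fwd, "forward", dilation),
         crnn_ti_forward(x, prev, pars_bwd, "backward", dilation))
}

# 3D convolution block (the Conv3D baseline variant): a k x k x kt kernel
# realised as kt spatial convolutions of temporally shifted copies
new_conv3d <- function(k, kt, cin, cout, name) {
  taps <- lapply(seq_len(kt), function(i)
    ad_param(.init_kernel(k, k, cin, cout), sprintf("%s.w%d", name, i)))
  list(taps = taps, b = ad_param(numeric(cout), paste0(name, ".b")), kt = kt)
}

conv3d_forward <- function(x, pars, dilation = 1L) {
  kt <- pars$kt
  half <- (kt - 1L) %/% 2L
  acc <- NULL
  for (i in seq_len(kt)) {
    h <- op_conv2d(x, ad_use(pars$taps[[i]]),
                   if (i == half + 1L) ad_use(pars$b) else NULL,
                   dilation = dilation)
    sh <- -(i - 1L - half)
    if (sh != 0L) h <- op_shift_time(h, sh, circular = FALSE)
    acc <- if (is.null(acc)) h else op_add(acc, h)
  }
  op_relu(acc)
}
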