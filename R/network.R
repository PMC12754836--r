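#' Configuration of the unrolled recurrent U-Net
#'
#' Collects every architectural switch of the reconstruction network: the
#' number of unrolled cascades, channel widths, kernel sizes, the dilation
#' triple for the two U-Net levels and the bottleneck, the ablation flags
#' (side branches, temporal circular padding, cross-cascade recurrence), the
#' data-consistency mode, and the network variant (`"crunet"` for the
#' recurrent U-Net, `"unet3d"` for the baseline in which every recurrent
#' unit is replaced by a 3D convolution block of matched width).
#'
#' @param n_cascades number of unrolled cascade blocks (default 5).
#' @param base_channels feature channels at the first U-Net level
#'   (default 48); the second level and bottleneck use
#'   `channel_growth * base_channels`.
#' @param kernel_size odd spatial kernel size (default 3).
#' @param temporal_kernel odd temporal kernel size of the Conv(2+1)D and
#'   Conv3D layers (default 3).
#' @param dilations length-3 integer vector: dilation at level 1, level 2,
#'   and the bottleneck (default `c(1, 2, 4)`).
#' @param use_side_branch keep the standard-convolution side branches next
#'   to each recurrent unit (default `TRUE`).
#' @param use_temporal_padding temporal circular padding in all Conv(2+1)D
#'   layers (default `TRUE`); when off, zero padding is used instead.
#' @param cross_cascade_recurrence propagate each level's merged feature map
#'   to the same level of the next cascade through a dedicated convolution
#'   (default `TRUE`); when off those kernels are absent entirely.
#' @param skip_merge how encoder features are merged into the decoder path:
#'   `"add"` (default, mirroring the bidirectional summation) or
#'   `"concat"`.
#' @param dc a [dc_params()] object.
#' @param variant `"crunet"` or `"unet3d"`.
#' @param channel_growth width multiplier from level 1 to level 2
#'   (default 2).
#' @param seed integer seed for weight initialization.
#' @return an object of class `crunet_config`.
#' @export
crunet_config <- function(n_cascades = 5L, base_channels = 48L,
                          kernel_size = 3L, temporal_kernel = 3L,
                          dilations = c(1L, 2L, 4L),
                          use_side_branch = TRUE,
                          use_temporal_padding = TRUE,
                          cross_cascade_recurrence = TRUE,
                          skip_merge = c("add", "concat"),
                          dc = dc_params(),
                          variant = c("crunet", "unet3d"),
                          channel_growth = 2L, seed = 1L) {
  skip_merge <- match.arg(skip_merge)
  variant <- match.arg(variant)
  stopifnot(n_cascades >= 1, base_channels >= 1,
            kernel_size %% 2 == 1, temporal_kernel %% 2 == 1,
            length(dilations) == 3, all(dilations >= 1))
  structure(list(
    n_cascades = as.integer(n_cascades),
    base_channels = as.integer(base_channels),
    kernel_size = as.integer(kernel_size),
    temporal_kernel = as.integer(temporal_kernel),
    dilations = as.integer(dilations),
    use_side_branch = isTRUE(use_side_branch),
    use_temporal_padding = isTRUE(use_temporal_padding),
    cross_cascade_recurrence = isTRUE(cross_cascade_recurrence),
    skip_merge = skip_merge, dc = dc, variant = variant,
    channel_growth = as.integer(channel_growth), seed = as.integer(seed)),
    class = "crunet_config")
}

# one recurrent (or Conv3D) unit plus its optional 1x1 side branch
.new_unit <- function(cfg, cin, chid, name) {
  k <- cfg$kernel_size
  u <- list()
  if (cfg$variant == "unet3d") {
    u$conv3d <- new_conv3d(k, cfg$temporal_kernel, cin, chid,
                           paste0(name, ".conv3d"))
  } else {
    u$crnn <- new_crnn_ti(k, cin, chid, cfg$cross_cascade_recurrence, name)
  }
  if (cfg$use_side_branch)
    u$side <- new_conv2d(1L, cin, chid, paste0(name, ".side"))
  u
}

.unit_forward <- function(x, prev, u, cfg, dilation, direction) {
  core <- if (!is.null(u$conv3d)) {
    conv3d_forward(x, u$conv3d, dilation = dilation)
  } else if (direction == "bidirectional") {
    bcrnn_ti_forward(x, prev, u$crnn$fwd, u$crnn$bwd, dilation = dilation)
  } else {
    crnn_ti_forward(x, prev, u$crnn, direction, dilation = dilation)
  }
  if (!is.null(u$side)) {
    core <- op_add(core, op_conv2d(x, ad_use(u$side$w), ad_use(u$side$b)))
  }
  core
}

.new_bi_unit <- function(cfg, cin, chid, name) {
  k <- cfg$kernel_size
  u <- list()
  if (cfg$variant == "unet3d") {
    u$conv3d <- new_conv3d(k, cfg$temporal_kernel, cin, chid,
                           paste0(name, ".conv3d"))
  } else {
    u$crnn <- list(
      fwd = new_crnn_ti(k, cin, chid, cfg$cross_cascade_recurrence,
                        paste0(name, ".fwd")),
      bwd = new_crnn_ti(k, cin, chid, cfg$cross_cascade_recurrence,
                        paste0(name, ".bwd")))
  }
  if (cfg$use_side_branch)
    u$side <- new_conv2d(1L, cin, chid, paste0(name, ".side"))
  u
}

#' Build a reconstruction network
#'
#' Instantiates all trainable parameters of the unrolled network described
#' by a [crunet_config()]. The cascade block weights are shared across the
#' unrolled cascades: the recurrence over the cascade index applies the same
#' unit at every iteration, which is what makes the cross-cascade
#' convolution a recurrence rather than a per-cascade skip connection.
#'
#' @param cfg a [crunet_config()].
#' @return an object of class `crunet_net` holding the parameters and the
#'   configuration.
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "crunet_config"))
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  k <- cfg$kernel_size; kt <- cfg$temporal_kernel
  C1 <- cfg$base_channels
  C2 <- C1 * cfg$channel_growth
  cat_f <- if (cfg$skip_merge == "concat") 2L else 1L
  p <- list(
    head = new_conv2d(k, 2L, C1, "head"),
    enc1 = .new_unit(cfg, C1, C1, "enc1"),
    down = new_conv2p1d(k, kt, C1, C2, "down"),
    enc2 = .new_unit(cfg, C2, C2, "enc2"),
    bottleneck = .new_bi_unit(cfg, C2, C2, "bottleneck"),
    bottleneck_out = new_conv2p1d(k, kt, C2, C2, "bottleneck_out"),
    dec2 = .new_unit(cfg, C2 * cat_f, C2, "dec2"),
    up = new_conv2p1d(k, kt, C2, C1, "up"),
    dec1 = .new_unit(cfg, C1 * cat_f, C1, "dec1"),
    tail = new_conv2d(k, C1, 2L, "tail"))
  if (cfg$dc$mode == "learnable") {
    p$dc_log_lambda <- lapply(seq_len(cfg$n_cascades), function(i)
      ad_param(cfg$dc$log_lambda0, sprintf("dc_log_lambda.%d", i)))
  }
  structure(list(config = cfg, params = p), class = "crunet_net")
}

# flatten the nested parameter list into a named list of ad_param
collect_params <- function(net) {
  out <- list()
  walk <- function(x) {
    if (inherits(x, "ad_param")) {
      out[[x$name]] <<- x
    } else if (is.list(x)) {
      for (el in x) walk(el)
    }
  }
  walk(net$params)
  out
}

#' Parameter inventory of a network
#'
#' @param net a [build_network()] object.
#' @return `network_summary`: data.frame with one row per parameter tensor
#'   (name, shape, element count); `network_param_count`: total number of
#'   trainable scalars.
#' @export
network_summary <- function(net) {
  ps <- collect_params(net)
  data.frame(
    name = names(ps),
    shape = vapply(ps, function(p)
      paste(if (is.null(dim(p$value))) length(p$value) else dim(p$value),
            collapse = "x"), character(1)),
    n = vapply(ps, function(p) length(p$value), numeric(1)),
    row.names = NULL)
}

#' @rdname network_summary
#' @export
network_param_count <- function(net) sum(network_summary(net)$n)

#' @export
print.crunet_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("crunet_net (%s): %d cascades, %d base channels, dilations (%s)\n",
              cfg$variant, cfg$n_cascades, cfg$base_channels,
              paste(cfg$dilations, collapse = ", ")))
  cat(sprintf("  %d parameter tensors, %d trainable values\n",
              nrow(network_summary(x)), network_param_count(x)))
  invisible(x)
}

# one cascade block: z-score -> head conv -> two-level recurrent U-Net with
# bottleneck -> tail conv -> un-normalize -> residual. Returns the block
# output and the cross-cascade feature bundle.
crunet_block_forward <- function(x, state, net) {
  cfg <- net$config
  p <- net$params
  d <- cfg$dilations
  circ <- cfg$use_temporal_padding
  dims <- dim(x$value)
  H <- dims[1]; W <- dims[2]
  He <- H + H %% 2L; We <- W + W %% 2L
  zs <- op_zscore(x)
  xp <- op_pad_hw(zs$node, He, We)

  h <- op_relu(op_conv2d(xp, ad_use(p$head$w), ad_use(p$head$b)))
  e1 <- .unit_forward(h, state$F1, p$enc1, cfg, d[1], "forward")
  dn <- conv2p1d_forward(e1, p$down, stride = 2L, dilation = 1L, circular = circ)
  e2 <- .unit_forward(dn, state$F2, p$enc2, cfg, d[2], "forward")
  bt <- .unit_forward(e2, state$Fb, p$bottleneck, cfg, d[3], "bidirectional")
  bt <- conv2p1d_forward(bt, p$bottleneck_out, dilation = d[3], circular = circ)

  merge <- function(a, b) {
    if (cfg$skip_merge == "concat") op_concat_c(a, b) else op_add(a, b)
  }
  dec2 <- .unit_forward(merge(bt, e2), state$F2, p$dec2, cfg, d[2], "backward")
  up <- conv2p1d_forward(op_upsample2(dec2), p$up, dilation = 1L, circular = circ)
  dec1 <- .unit_forward(merge(up, e1), state$F1, p$dec1, cfg, d[1], "backward")

  out <- op_conv2d(dec1, ad_use(p$tail$w), ad_use(p$tail$b))
  out <- op_crop_hw(out, H, W)
  z <- op_add(op_zscore_un(out, zs$mean, zs$sd), x)
  new_state <- if (cfg$variant == "crunet" && cfg$cross_cascade_recurrence) {
    list(F1 = op_add(e1, dec1), F2 = op_add(e2, dec2), Fb = bt)
  } else NULL
  list(z = z, state = new_state)
}

# full unrolled forward pass on the tape; y is normalized complex k-space
crunet_forward_tape <- function(net, y, S, mask, return_intermediates = FALSE) {
  cfg <- net$config
  mask <- as_sampling_mask(mask)
  x0 <- adjoint_A(y, S, mask)
  x <- ad_const(cplx_to_net(x0))
  state <- NULL
  inter <- if (return_intermediates) list() else NULL
  for (i in seq_len(cfg$n_cascades)) {
    blk <- crunet_block_forward(x, state, net)
    state <- blk$state
    ll <- if (cfg$dc$mode == "learnable")
      ad_use(net$params$dc_log_lambda[[i]]) else NULL
    x <- op_dc(blk$z, y, S, mask, cfg$dc, ll)
    if (return_intermediates) inter[[i]] <- net_to_cplx(x$value)
  }
  list(x = x, x0 = x0, kspace = x$kspace, intermediates = inter)
}

#' Run the unrolled network on undersampled k-space
#'
#' Computes the zero-filled initialization `A^H y`, then alternates the
#' recurrent U-Net block and the k-space data-consistency step for the
#' configured number of cascades. No normalization is applied here; pass
#' k-space already scaled by [maxabs_normalize()] (as during training) and
#' rescale the output with the returned factor.
#'
#' @param net a [build_network()] object.
#' @param y complex multi-coil k-space `(T, C, H, W)`.
#' @param S coil sensitivity maps `(C, H, W)`.
#' @param mask a [make_mask()] object or pattern matrix.
#' @param return_intermediates also return every cascade's output.
#' @return list with `x` (complex `(T, H, W)` reconstruction), `x0` (the
#'   zero-filled initialization), `kspace` (the final data-consistency
#'   step's per-coil k-space `y_rec`, in which the acquired samples are
#'   preserved exactly in hard mode) and optionally `intermediates`.
#' @export
crunet_forward <- function(net, y, S, mask, return_intermediates = FALSE) {
  res <- crunet_forward_tape(net, y, S, mask, return_intermediates)
  list(x = net_to_cplx(res$x$value), x0 = res$x0, kspace = res$kspace,
       intermediates = res$intermediates)
}
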