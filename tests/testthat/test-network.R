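ns <- asNamespace("cinerecon")

small_net <- function(...) build_network(crunet_config(
  n_cascades = 2L, base_channels = 4L, seed = 11L, ...))

small_scene <- function(H = 16L, W = 16L, T = 4L, C = 2L, seed = 51L) {
  sp <- phantom_spec(T = T, H = H, W = W, n_coils = C, seed = seed)
  x <- make_phantom(sp)$img
  S <- make_coil_maps(sp)
  m <- make_mask(H, W, 2L, acs_lines = 4L)
  y <- maxabs_normalize(simulate_acquisition(x, S, m, 0)$y)$y
  list(x = x, S = S, mask = m, y = y)
}

test_that("every cascade preserves the sequence shape, even for odd sizes", {
  for (hw in list(c(16L, 16L), c(12L, 10L), c(9L, 7L))) {
    sc <- small_scene(H = hw[1], W = hw[2])
    out <- crunet_forward(small_net(), sc$y, sc$S, sc$mask)
    expect_equal(dim(out$x), c(4L, hw))
    expect_equal(dim(out$x0), c(4L, hw))
  }
})

test_that("a zeroed tail convolution makes the block a residual identity", {
  sc <- small_scene()
  net <- small_net()
  net$params$tail$w$value[] <- 0
  net$params$tail$b$value[] <- 0
  x0 <- adjoint_A(sc$y, sc$S, sc$mask)
  x0c <- x0 - mean(c(Re(x0), Im(x0))) * (1 + 1i)   # zero-mean input
  xin <- ns$ad_const(cplx_to_net(x0c))
  blk <- ns$crunet_block_forward(xin, NULL, net)
  expect_lt(max(abs(blk$z$value - xin$value)), 1e-10)
})

test_that("full sampling plus hard DC returns the ground truth exactly", {
  sp <- phantom_spec(T = 4, H = 16, W = 16, n_coils = 2, seed = 52)
  x <- make_phantom(sp)$img
  S <- make_coil_maps(sp)
  mf <- make_mask(16, 16, 1, acs_lines = 0)
  y <- simulate_acquisition(x, S, mf, 0)$y
  for (variant in c("crunet", "unet3d")) {
    net <- build_network(crunet_config(n_cascades = 2L, base_channels = 4L,
                                       seed = 3L, variant = variant))
    out <- crunet_forward(net, y, S, mf)
    expect_lt(max(Mod(out$x - x)) / max(Mod(x)), 1e-8)
  }
})

test_that("hard DC preserves acquired k-space for both variants", {
  sc <- small_scene()
  keep <- sc$mask$acquired_rows + 1L
  for (variant in c("crunet", "unet3d")) {
    net <- build_network(crunet_config(n_cascades = 2L, base_channels = 4L,
                                       seed = 7L, variant = variant))
    out <- crunet_forward(net, sc$y, sc$S, sc$mask)
    resid <- max(Mod(out$kspace[, , keep, ] - sc$y[, , keep, ])) /
             max(Mod(sc$y))
    expect_lt(resid, 1e-6)
  }
})

test_that("finite nonzero gradients reach every trainable parameter", {
  sc <- small_scene()
  for (variant in c("crunet", "unet3d")) {
    net <- build_network(crunet_config(n_cascades = 2L, base_channels = 4L,
                                       seed = 9L, variant = variant))
    ps <- ns$collect_params(net)
    for (p in ps) p$grad <- NULL
    ns$ad_tape_begin()
    fwd <- ns$crunet_forward_tape(net, sc$y, sc$S, sc$mask)
    loss <- ns$total_loss_node(fwd$x, cplx_to_net(sc$x), loss_weights())
    ns$ad_backward(loss)
    ns$ad_tape_end()
    ok <- vapply(ps, function(p)
      !is.null(p$grad) && all(is.finite(p$grad)) && any(p$grad != 0),
      logical(1))
    expect_true(all(ok), info = paste(names(ps)[!ok], collapse = ", "))
  }
})

test_that("a single-frame feed-forward block matches straight-line algebra", {
  # T = 1 with cross-cascade recurrence off: every recurrent unit collapses
  # to conv + ReLU, so the whole block can be re-evaluated with the
  # brute-force convolution oracle, layer by layer.
  set.seed(53)
  net <- build_network(crunet_config(n_cascades = 1L, base_channels = 4L,
                                     cross_cascade_recurrence = FALSE,
                                     seed = 13L))
  p <- net$params
  xin_c <- rcplx(c(1, 8, 8))
  x <- cplx_to_net(xin_c)
  blk <- ns$crunet_block_forward(ns$ad_const(x), NULL, net)

  v <- as.numeric(x)
  m <- mean(v); s <- stats::sd(v)
  xn <- (x - m) / s
  relu <- function(a) pmax(a, 0)
  conv <- function(a, pp, stride = 1, dil = 1)
    brute_conv2d(a, pp$w$value, pp$b$value, stride, dil)
  # single-frame Conv(2+1)D: temporal taps all see the same frame under
  # circular padding, so they sum
  conv2p1d_1f <- function(a, pp, stride = 1, dil = 1) {
    h <- conv(a, pp$spatial, stride, dil)
    tw <- pp$temporal$w$value
    co <- dim(tw)[3]
    out <- h * 0
    for (o in seq_len(co)) {
      acc <- matrix(pp$temporal$b$value[o], dim(h)[1], dim(h)[2])
      for (k in 1:dim(tw)[1]) for (ci in seq_len(dim(tw)[2]))
        acc <- acc + tw[k, ci, o] * h[, , ci, 1]
      out[, , o, 1] <- acc
    }
    relu(out)
  }
  unit <- function(a, u, dil) {
    core <- relu(conv(a, list(w = u$crnn$w_l, b = u$crnn$b), dil = dil))
    core + conv(a, u$side)
  }
  d <- net$config$dilations
  h <- relu(conv(xn, p$head))
  e1 <- unit(h, p$enc1, d[1])
  dn <- conv2p1d_1f(e1, p$down, stride = 2)
  e2 <- unit(dn, p$enc2, d[2])
  bt_core <- relu(conv(e2, list(w = p$bottleneck$crnn$fwd$w_l,
                                b = p$bottleneck$crnn$fwd$b), dil = d[3])) +
             relu(conv(e2, list(w = p$bottleneck$crnn$bwd$w_l,
                                b = p$bottleneck$crnn$bwd$b), dil = d[3]))
  bt <- bt_core + conv(e2, p$bottleneck$side)
  bt <- conv2p1d_1f(bt, p$bottleneck_out, dil = d[3])
  dec2 <- unit(bt + e2, p$dec2, d[2])
  upsampled <- dec2[rep(1:4, each = 2), rep(1:4, each = 2), , , drop = FALSE]
  up <- conv2p1d_1f(upsampled, p$up)
  dec1 <- unit(up + e1, p$dec1, d[1])
  out <- conv(dec1, p$tail)
  ref <- out * s + m + x
  expect_lt(max(abs(blk$z$value - ref)), 1e-6)
})

test_that("ablation switches change the parameter inventory as specified", {
  base <- network_summary(small_net())
  no_side <- network_summary(small_net(use_side_branch = FALSE))
  no_cross <- network_summary(small_net(cross_cascade_recurrence = FALSE))
  no_pad <- network_summary(small_net(use_temporal_padding = FALSE))
  expect_gt(sum(grepl("side", base$name)), 0)
  expect_equal(sum(grepl("side", no_side$name)), 0)
  expect_gt(sum(grepl("w_i", base$name)), 0)
  expect_equal(sum(grepl("w_i", no_cross$name)), 0)
  # temporal padding is connectivity, not parameters
  expect_equal(no_pad$n, base$n)
  # the Conv3D variant has a different parameter count at equal width
  u3 <- network_summary(small_net(variant = "unet3d"))
  expect_false(sum(u3$n) == sum(base$n))
  expect_equal(sum(grepl("w_t|w_i", u3$name)), 0)
})

test_that("weight sharing: parameter count is independent of cascade depth", {
  n2 <- network_param_count(build_network(crunet_config(
    n_cascades = 2L, base_channels = 4L, seed = 1L)))
  n5 <- network_param_count(build_network(crunet_config(
    n_cascades = 5L, base_channels = 4L, seed = 1L)))
  expect_equal(n2, n5)
})
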