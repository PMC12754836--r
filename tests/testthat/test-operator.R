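test_that("coil combine after expand is the identity for unit-SOS maps", {
  set.seed(5)
  sc <- toy_scene()
  sos <- apply(Mod(sc$S)^2, c(2, 3), sum)
  expect_lt(max(abs(sos - 1)), 1e-10)
  x <- rcplx(c(3, 12, 12))
  expect_lt(max(Mod(coil_combine(coil_expand(x, sc$S), sc$S) - x)), 1e-10)
  # single coil with S = 1 is the identity both ways
  S1 <- array(1 + 0i, c(1, 4, 4)); x1 <- rcplx(c(2, 4, 4))
  expect_equal(coil_combine(coil_expand(x1, S1), S1), x1)
  expect_error(coil_expand(x1, sc$S), "mismatch")
})

test_that("forward and adjoint operators pass the inner-product test", {
  set.seed(6)
  worst <- 0
  for (i in 1:100) {
    C <- sample(1:3, 1); T_ <- sample(1:2, 1)
    # adjointness holds for arbitrary (not only unit-SOS) maps
    S <- rcplx(c(C, 6, 6))
    m <- make_mask(6, 6, sample(1:3, 1), acs_lines = sample(0:2, 1))
    x <- rcplx(c(T_, 6, 6)); y <- rcplx(c(T_, C, 6, 6))
    lhs <- sum(Re(Conj(forward_A(x, S, m)) * y))
    rhs <- sum(Re(Conj(x) * adjoint_A(y, S, m)))
    worst <- max(worst, abs(lhs - rhs) / max(abs(lhs), abs(rhs)))
  }
  expect_lt(worst, 1e-8)
})

test_that("full sampling inverts the forward model exactly", {
  sc <- toy_scene()
  mf <- make_mask(12, 12, 1, acs_lines = 0)
  y <- forward_A(sc$x, sc$S, mf)
  expect_lt(max(Mod(adjoint_A(y, sc$S, mf) - sc$x)), 1e-8)
  expect_true(all(forward_A(0 * sc$x, sc$S, mf) == 0))
  expect_true(all(adjoint_A(0 * y, sc$S, mf) == 0))
})

test_that("data consistency matches the per-index brute-force evaluation", {
  set.seed(7)
  for (i in 1:5) {
    sp <- phantom_spec(T = 2, H = 8, W = 8, n_coils = 2, seed = i + 20)
    S <- make_coil_maps(sp)
    m <- make_mask(8, 8, 2, acs_lines = 2)
    z <- rcplx(c(2, 8, 8))
    y <- apply_mask_for_test(rcplx(c(2, 2, 8, 8)), m)
    for (l0 in c(Inf, 1, 0.3)) {
      got <- if (is.infinite(l0)) {
        data_consistency(z, y, S, m, dc_params(), return_kspace = TRUE)
      } else {
        data_consistency(z, y, S, m, dc_params(l0, "learnable"),
                         return_kspace = TRUE)
      }
      ref <- brute_dc(z, y, S, m, l0)
      expect_lt(max(Mod(got$image - ref$image)), 1e-10)
      expect_lt(max(Mod(got$kspace - ref$kspace)), 1e-10)
    }
  }
})

test_that("hard DC preserves acquired samples; small lambda returns z", {
  set.seed(8)
  sc <- toy_scene()
  y <- simulate_acquisition(sc$x, sc$S, sc$mask, 0)$y
  z <- sc$x + 0.2 * rcplx(dim(sc$x))
  out <- data_consistency(z, y, sc$S, sc$mask, dc_params(),
                          return_kspace = TRUE)
  keep <- sc$mask$acquired_rows + 1L
  expect_lt(max(Mod(out$kspace[, , keep, ] - y[, , keep, ])) / max(Mod(y)),
            1e-12)
  # lambda -> 0: the blend returns the network output unchanged
  out0 <- data_consistency(z, y, sc$S, sc$mask, dc_params(1e-12, "learnable"))
  expect_lt(max(Mod(out0 - z)), 1e-8)
})

test_that("a consistent (z, y) pair makes image-level hard DC idempotent", {
  sc <- toy_scene()
  y <- simulate_acquisition(sc$x, sc$S, sc$mask, 0)$y
  once <- data_consistency(sc$x, y, sc$S, sc$mask, dc_params())
  twice <- data_consistency(once, y, sc$S, sc$mask, dc_params())
  expect_lt(max(Mod(once - sc$x)), 1e-10)        # already consistent
  expect_lt(max(Mod(twice - once)), 1e-8)
  # and k-space-level idempotence holds for arbitrary z
  z <- sc$x + 0.3 * rcplx(dim(sc$x))
  k1 <- data_consistency(z, y, sc$S, sc$mask, dc_params(),
                         return_kspace = TRUE)$kspace
  img1 <- coil_combine(ifft2c(k1), sc$S)
  k2 <- data_consistency(img1, y, sc$S, sc$mask, dc_params(),
                         return_kspace = TRUE)$kspace
  keep <- sc$mask$acquired_rows + 1L
  expect_lt(max(Mod(k2[, , keep, ] - k1[, , keep, ])), 1e-10)
})

test_that("scalar blend example: k_z = 2, y = 4, lambda0 = 1 gives 3", {
  # one frame, one coil, flat unit map; one acquired row
  S1 <- array(1 + 0i, c(1, 4, 4))
  m <- make_mask(4, 4, 4, acs_lines = 0, offset = 1)   # row 1 only
  z <- ifft2c(array(2 + 0i, c(1, 4, 4)))               # k_z = 2 everywhere
  y <- array(0i, c(1, 1, 4, 4)); y[1, 1, 2, ] <- 4     # y = 4 on acquired row
  out <- data_consistency(z, y, S1, m, dc_params(1, "learnable"),
                          return_kspace = TRUE)
  expect_lt(max(Mod(out$kspace[1, 1, 2, ] - 3)), 1e-12)
  expect_lt(max(Mod(out$kspace[1, 1, c(1, 3, 4), ] - 2)), 1e-12)
})

test_that("max-abs normalization is scale-equivariant with unit peak", {
  set.seed(9)
  y <- rcplx(c(2, 2, 8, 8))
  nz <- maxabs_normalize(y)
  expect_lt(abs(max(Mod(ifft2c(nz$y))) - 1), 1e-12)
  nz7 <- maxabs_normalize(7 * y)
  expect_lt(max(Mod(nz7$y - nz$y)), 1e-12)
  expect_equal(nz7$scale, 7 * nz$scale)
  expect_equal(maxabs_normalize(nz$y)$scale, 1)
  expect_error(maxabs_normalize(0 * y), "all-zero")
})

test_that("z-score round-trips and clamps constant input", {
  set.seed(10)
  x <- array(rnorm(60, 5, 3), c(3, 4, 5))
  zs <- zscore_norm(x)
  expect_lt(abs(mean(zs$x)), 1e-10)
  expect_lt(abs(stats::sd(as.numeric(zs$x)) - 1), 1e-6)
  expect_lt(max(abs(zscore_unnorm(zs$x, zs$mean, zs$sd) - x)), 1e-10)
  zc <- zscore_norm(array(4, c(2, 2)))
  expect_true(all(zc$x == 0))
  xc <- rcplx(c(2, 3, 3))
  zs2 <- zscore_norm(xc)
  expect_lt(max(Mod(zscore_unnorm(zs2$x, zs2$mean, zs2$sd) - xc)), 1e-10)
})
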