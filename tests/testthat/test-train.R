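tiny_setup <- function(dir, n_train = 2, n_val = 1, seed = 81) {
  sp <- phantom_spec(T = 4, H = 16, W = 16, n_coils = 2, noise_sigma = 0.01,
                     seed = seed)
  spv <- sp; spv$seed <- seed + 1000L
  m <- make_mask(16, 16, 2, acs_lines = 4)
  make_dataset(n_train, sp, m, file.path(dir, "train"))
  make_dataset(n_val, spv, m, file.path(dir, "val"))
  list(train = file.path(dir, "train"), val = file.path(dir, "val"))
}

test_that("the warm-up/cosine schedule has the required shape", {
  cfg <- train_config(epochs = 30, lr = 3e-4, lr_floor = 1e-4,
                      warmup_epochs = 10)
  lrs <- sapply(1:30, lr_schedule, cfg = cfg)
  expect_true(all(diff(lrs[1:10]) >= 0))        # non-decreasing warm-up
  expect_true(all(diff(lrs[10:30]) <= 0))       # non-increasing decay
  expect_true(all(lrs >= 1e-4 - 1e-15))
  expect_equal(lrs[10], 3e-4)
  expect_equal(lrs[30], 1e-4)
  expect_error(train_config(lr = 1e-4, lr_floor = 3e-4))
})

test_that("a short training run learns and is fully reproducible", {
  dirs <- tiny_setup(tempfile("tr"))
  ckpt <- tempfile(fileext = ".rds")
  run <- function() {
    net <- build_network(crunet_config(n_cascades = 1L, base_channels = 4L,
                                       seed = 5L))
    cfg <- train_config(epochs = 25, warmup_epochs = 3, lr = 1e-3,
                        lr_floor = 3e-4, seed = 5, checkpoint = ckpt)
    train_model(net, dirs$train, dirs$val, cfg)
  }
  fit1 <- run()
  # the loss trace must drop: mean of the last epoch below the first step
  expect_lt(mean(tail(fit1$step_loss, 4)), fit1$step_loss[1])
  expect_true(all(is.finite(fit1$step_loss)))
  expect_true(file.exists(ckpt))
  expect_true(is.finite(fit1$best$ssim))
  # bit-for-bit reproducibility under the same master seed
  fit2 <- run()
  expect_identical(fit1$step_loss, fit2$step_loss)
  expect_identical(fit1$history$val_ssim, fit2$history$val_ssim)
})

test_that("checkpoints round-trip and reconstructions are deterministic", {
  dirs <- tiny_setup(tempfile("tr"), n_train = 1, n_val = 1, seed = 91)
  net <- build_network(crunet_config(n_cascades = 1L, base_channels = 4L,
                                     seed = 6L))
  ckpt <- tempfile(fileext = ".rds")
  save_checkpoint(net, ckpt, extra = list(tag = 1))
  lk <- load_checkpoint(ckpt)
  expect_equal(lk$extra$tag, 1)
  f <- list.files(dirs$val, pattern = "\\.rds$", full.names = TRUE)[1]
  slice <- read_slice(f)
  r1 <- reconstruct_slice(lk$net, slice)
  r2 <- reconstruct_slice(lk$net, f)
  expect_identical(r1$recon, r2$recon)
  expect_equal(dim(r1$recon), dim(slice$ground_truth))
  # acquired lines of the reconstruction's k-space equal the measurements
  keep <- slice$mask$acquired_rows + 1L
  resid <- max(Mod(r1$kspace[, , keep, ] - slice$kspace[, , keep, ])) /
           max(Mod(slice$kspace))
  expect_lt(resid, 1e-6)
})

test_that("evaluation reports sane global and region metrics as JSON", {
  dirs <- tiny_setup(tempfile("tr"), n_train = 1, n_val = 2, seed = 95)
  net <- build_network(crunet_config(n_cascades = 1L, base_channels = 4L,
                                     seed = 7L))
  ev <- evaluate_dataset(net, dirs$val)
  expect_equal(nrow(ev$per_slice), 2)
  expect_equal(ev$aggregate$mean$psnr, mean(ev$per_slice$psnr))
  js <- jsonlite::toJSON(ev$aggregate, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$mean$ssim, ev$aggregate$mean$ssim, tolerance = 1e-9)
  expect_error(evaluate_dataset(net, tempfile()), "no slice containers")
})

test_that("slice containers validate shapes and round-trip", {
  sc <- toy_scene(T = 2L, H = 8L, W = 8L, C = 2L)
  y <- simulate_acquisition(sc$x[1:2, , ], sc$S, sc$mask, 0)$y
  p <- tempfile(fileext = ".rds")
  write_slice(p, y, sc$S, sc$mask, sc$x[1:2, , ], attrs = list(seed = 1))
  s <- read_slice(p)
  expect_identical(s$kspace, y)
  expect_identical(s$ground_truth, sc$x[1:2, , ])
  expect_equal(s$attrs$seed, 1)
  expect_error(write_slice(p, y, sc$S[, 1:4, ], sc$mask), "inconsistent")
})

test_that("network configurations round-trip through config files", {
  cfg <- crunet_config(n_cascades = 3, base_channels = 16,
                       dilations = c(1, 3, 5), use_side_branch = FALSE,
                       dc = dc_params(50, "learnable"), seed = 9)
  p <- tempfile(fileext = ".json")
  write_config(cfg, p)
  back <- read_config(p)
  expect_equal(back$dilations, cfg$dilations)
  expect_equal(back$use_side_branch, FALSE)
  expect_equal(back$dc$mode, "learnable")
  expect_equal(exp(back$dc$log_lambda0), 50, tolerance = 1e-12)
  expect_equal(network_param_count(build_network(back)),
               network_param_count(build_network(cfg)))
})
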