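#' Training configuration
#'
#' AdamW (decoupled weight decay) with a warm-up plus cosine-annealing
#' learning-rate schedule, batch size one slice, gradient clipping at unit
#' global norm, and the composite k-space/image/SSIM loss.
#'
#' @param epochs number of passes over the training set.
#' @param lr initial (post-warm-up peak) learning rate (default 3e-4).
#' @param lr_floor minimum learning rate of the cosine schedule
#'   (default 1e-4).
#' @param warmup_epochs linear warm-up epochs (default 10).
#' @param weight_decay decoupled weight decay (default 0.01).
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @param clip_norm global gradient-norm clip (default 1).
#' @param loss a [loss_weights()] object.
#' @param seed master seed controlling initialization and data order.
#' @param checkpoint optional path; the parameters with the best validation
#'   SSIM are saved there.
#' @param shuffle reshuffle the slice order each epoch (seeded).
#' @param verbose print one line per epoch.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 30L, lr = 3e-4, lr_floor = 1e-4,
                         warmup_epochs = 10L, weight_decay = 0.01,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         clip_norm = 1, loss = loss_weights(), seed = 1L,
                         checkpoint = NULL, shuffle = TRUE, verbose = FALSE) {
  stopifnot(epochs >= 1, lr > 0, lr_floor <= lr, warmup_epochs >= 0)
  structure(list(epochs = as.integer(epochs), lr = lr, lr_floor = lr_floor,
                 warmup_epochs = as.integer(warmup_epochs),
                 weight_decay = weight_decay, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, clip_norm = clip_norm, loss = loss,
                 seed = as.integer(seed), checkpoint = checkpoint,
                 shuffle = isTRUE(shuffle), verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Linear warm-up from the floor to the peak over the first
#' `warmup_epochs` epochs, then cosine annealing back down to the floor.
#' The rate is non-decreasing during warm-up, non-increasing afterwards,
#' and never falls below the floor.
#'
#' @param epoch 1-based epoch index.
#' @param cfg a [train_config()].
#' @return learning rate.
#' @export
lr_schedule <- function(epoch, cfg) {
  w <- cfg$warmup_epochs
  if (w > 0 && epoch <= w)
    return(cfg$lr_floor + (cfg$lr - cfg$lr_floor) * epoch / w)
  n_decay <- max(cfg$epochs - w, 1L)
  frac <- min((epoch - w - 1) / max(n_decay - 1, 1L), 1)
  cfg$lr_floor + 0.5 * (cfg$lr - cfg$lr_floor) * (1 + cos(pi * frac))
}

# one AdamW update over a named list of ad_param; state kept in `opt`
.adamw_step <- function(params, opt, lr, cfg) {
  gn2 <- 0
  for (p in params) if (!is.null(p$grad)) gn2 <- gn2 + sum(p$grad^2)
  scale <- if (cfg$clip_norm > 0 && sqrt(gn2) > cfg$clip_norm)
    cfg$clip_norm / sqrt(gn2) else 1
  opt$t <- opt$t + 1L
  b1 <- cfg$beta1; b2 <- cfg$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- if (is.null(p$grad)) 0 * p$value else p$grad * scale
    if (is.null(opt$m[[nm]])) {
      opt$m[[nm]] <- 0 * p$value
      opt$v[[nm]] <- 0 * p$value
    }
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    step <- (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + cfg$adam_eps)
    p$value <- p$value - lr * (step + cfg$weight_decay * p$value)
    p$grad <- NULL
  }
  sqrt(gn2)
}

# load a slice and prepare normalized tensors for one training/eval step
.prep_slice <- function(slice) {
  nz <- maxabs_normalize(slice$kspace)
  gt <- slice$ground_truth / nz$scale
  list(y = nz$y, S = slice$sensitivity, mask = slice$mask,
       gnd2 = cplx_to_net(gt), gt = gt, scale = nz$scale)
}

#' Train a reconstruction network
#'
#' Runs the unrolled network end to end on a directory of slice containers:
#' per step, one slice is loaded, max-abs normalized, reconstructed from its
#' zero-filled initialization, scored with the composite loss against the
#' (identically scaled) ground truth, and the shared block weights updated
#' by AdamW with warm-up/cosine learning rates and unit-norm gradient
#' clipping. Validation PSNR/SSIM are computed each epoch; the checkpoint
#' with the best validation SSIM is kept. Fully seeded: a fixed
#' configuration reproduces the loss trace exactly.
#'
#' @param net a [build_network()] object (modified in place and returned).
#' @param train_dir directory of training slice containers.
#' @param val_dir optional directory of validation slices.
#' @param cfg a [train_config()].
#' @return list with `net`, `history` (data.frame: epoch, lr, mean train
#'   loss, validation PSNR/SSIM), `step_loss` (per-step loss trace) and
#'   `best` (best validation epoch and metrics).
#' @export
train_model <- function(net, train_dir, val_dir = NULL, cfg = train_config()) {
  files <- list.files(train_dir, pattern = "\\.rds$", full.names = TRUE)
  if (length(files) == 0) stop("no slice containers in ", train_dir)
  val_files <- if (!is.null(val_dir))
    list.files(val_dir, pattern = "\\.rds$", full.names = TRUE) else character(0)
  params <- collect_params(net)
  opt <- new.env(parent = emptyenv()); opt$t <- 0L; opt$m <- list(); opt$v <- list()
  set.seed(cfg$seed)
  history <- NULL
  step_loss <- numeric(0)
  best <- list(ssim = -Inf, epoch = NA_integer_)
  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_schedule(epoch, cfg)
    order <- if (cfg$shuffle) sample(seq_along(files)) else seq_along(files)
    ep_losses <- numeric(0)
    for (fi in order) {
      sl <- .prep_slice(read_slice(files[fi]))
      ad_tape_begin()
      fwd <- crunet_forward_tape(net, sl$y, sl$S, sl$mask)
      loss <- total_loss_node(fwd$x, sl$gnd2, cfg$loss)
      lv <- loss$value
      if (!is.finite(lv)) {
        ad_tape_end()
        stop(sprintf("non-finite loss at epoch %d (file %s): %g",
                     epoch, basename(files[fi]), lv))
      }
      ad_backward(loss)
      ad_tape_end()
      .adamw_step(params, opt, lr, cfg)
      ep_losses <- c(ep_losses, lv)
    }
    step_loss <- c(step_loss, ep_losses)
    val <- c(psnr = NA_real_, ssim = NA_real_)
    if (length(val_files) > 0) {
      vp <- vs <- numeric(length(val_files))
      for (i in seq_along(val_files)) {
        sl <- .prep_slice(read_slice(val_files[i]))
        rec <- crunet_forward(net, sl$y, sl$S, sl$mask)$x
        vp[i] <- psnr(rec, sl$gt)
        vs[i] <- ssim_eval(rec, sl$gt)
      }
      val <- c(psnr = mean(vp), ssim = mean(vs))
      if (val["ssim"] > best$ssim) {
        best <- list(ssim = unname(val["ssim"]), psnr = unname(val["psnr"]),
                     epoch = epoch)
        if (!is.null(cfg$checkpoint))
          save_checkpoint(net, cfg$checkpoint,
                          extra = list(epoch = epoch, val = val,
                                       seed = cfg$seed))
      }
    }
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, train_loss = mean(ep_losses),
      val_psnr = unname(val["psnr"]), val_ssim = unname(val["ssim"])))
    if (cfg$verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.5f  val PSNR %.2f  SSIM %.4f",
                      epoch, lr, mean(ep_losses), val["psnr"], val["ssim"]))
  }
  if (is.null(cfg$checkpoint) || !is.finite(best$ssim)) {
    if (!is.null(cfg$checkpoint))
      save_checkpoint(net, cfg$checkpoint,
                      extra = list(epoch = cfg$epochs, seed = cfg$seed))
  }
  list(net = net, history = history, step_loss = step_loss, best = best)
}

#' Reconstruct a slice with a trained network
#'
#' Normalizes the slice's k-space by its peak image magnitude, runs the
#' unrolled network, and rescales the output back to the physical range.
#'
#' @param net a [build_network()] object (e.g. from [load_checkpoint()]).
#' @param slice a [read_slice()] container (or path to one).
#' @return list with `recon` (complex `(T, H, W)`), `magnitude`, `kspace`
#'   (the reconstruction's per-coil k-space `y_rec`, acquired samples
#'   preserved exactly under hard data consistency), `zero_filled`
#'   (rescaled initialization) and `scale`.
#' @export
reconstruct_slice <- function(net, slice) {
  if (is.character(slice)) slice <- read_slice(slice)
  sl <- .prep_slice2(slice)
  fwd <- crunet_forward(net, sl$y, sl$S, sl$mask)
  rec <- fwd$x * sl$scale
  list(recon = rec, magnitude = Mod(rec), kspace = fwd$kspace * sl$scale,
       zero_filled = fwd$x0 * sl$scale, scale = sl$scale)
}

# like .prep_slice but without requiring ground truth
.prep_slice2 <- function(slice) {
  nz <- maxabs_normalize(slice$kspace)
  list(y = nz$y, S = slice$sensitivity, mask = slice$mask, scale = nz$scale)
}

#' Evaluate reconstructions against ground truth
#'
#' Computes global and region PSNR/SSIM for every slice in a directory
#' (each container must include its ground truth) and aggregates them as
#' mean and standard deviation.
#'
#' @param net a trained network.
#' @param dir directory of slice containers.
#' @param percentile dynamic-region percentile (default 90).
#' @return list with `per_slice` (data.frame) and `aggregate` (named means
#'   and standard deviations), suitable for JSON serialization.
#' @export
evaluate_dataset <- function(net, dir, percentile = 90) {
  files <- list.files(dir, pattern = "\\.rds$", full.names = TRUE)
  if (length(files) == 0) stop("no slice containers in ", dir)
  rows <- NULL
  for (f in files) {
    slice <- read_slice(f)
    if (is.null(slice$ground_truth)) stop("no ground truth in ", f)
    rec <- reconstruct_slice(net, slice)$recon
    gt <- slice$ground_truth
    rm_ <- dynamic_mask(gt, percentile)
    reg <- region_metrics(rec, gt, rm_)
    rows <- rbind(rows, data.frame(
      file = basename(f),
      psnr = psnr(rec, gt), ssim = ssim_eval(rec, gt),
      psnr_dynamic = reg$dynamic["psnr"], ssim_dynamic = reg$dynamic["ssim"],
      psnr_static = reg$static["psnr"], ssim_static = reg$static["ssim"],
      row.names = NULL))
  }
  num <- rows[, setdiff(names(rows), "file")]
  aggregate <- list(mean = as.list(colMeans(num)),
                    sd = as.list(apply(num, 2, stats::sd)))
  list(per_slice = rows, aggregate = aggregate)
}
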