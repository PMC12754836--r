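#' Slice containers
#'
#' One container per slice holds everything needed to reconstruct and
#' evaluate it: the (undersampled) multi-coil k-space `(T, C, H, W)`, the
#' coil sensitivity maps `(C, H, W)`, the sampling mask, optionally the
#' fully sampled ground-truth image sequence `(T, H, W)`, and a free-form
#' attribute list (nominal acceleration, ACS line count, seed, ...).
#' Containers are stored as single RDS files and round-trip bit-exactly.
#'
#' @param path file path (conventionally `.rds`).
#' @param kspace complex array `(T, C, H, W)`.
#' @param sensitivity complex array `(C, H, W)`.
#' @param mask a [make_mask()] object or pattern matrix.
#' @param ground_truth optional complex array `(T, H, W)`.
#' @param attrs named list of attributes.
#' @return `write_slice`: the path, invisibly; `read_slice`: the container
#'   list (class `cine_slice`).
#' @export
write_slice <- function(path, kspace, sensitivity, mask, ground_truth = NULL,
                        attrs = list()) {
  mask <- as_sampling_mask(mask)
  dk <- dim(kspace)
  if (length(dk) != 4) stop("kspace must be (T, C, H, W)")
  if (!all(dim(sensitivity) == c(dk[2], dk[3], dk[4])))
    stop("sensitivity shape inconsistent with kspace")
  if (!is.null(ground_truth) && !all(dim(ground_truth) == dk[c(1, 3, 4)]))
    stop("ground_truth shape inconsistent with kspace")
  obj <- structure(list(kspace = kspace, sensitivity = sensitivity,
                        mask = mask, ground_truth = ground_truth,
                        attrs = attrs), class = "cine_slice")
  saveRDS(obj, path, version = 3)
  invisible(path)
}

#' @rdname write_slice
#' @export
read_slice <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "cine_slice")) stop("not a cine slice container: ", path)
  obj
}

#' @export
print.cine_slice <- function(x, ...) {
  d <- dim(x$kspace)
  cat(sprintf("cine_slice: %d frames, %d coils, %d x %d%s\n", d[1], d[2],
              d[3], d[4],
              if (is.null(x$ground_truth)) "" else ", with ground truth"))
  invisible(x)
}

#' Read or write a network configuration file
#'
#' Serializes a [crunet_config()] to JSON (always available) or YAML (if
#' the yaml package is installed), chosen by file extension, and restores
#' it including the data-consistency parameters.
#'
#' @param cfg a [crunet_config()].
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "crunet_config"))
  x <- unclass(cfg)
  x$dc <- list(lambda0 = exp(cfg$dc$log_lambda0), mode = cfg$dc$mode)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    writeLines(yaml::as.yaml(x), path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  dc <- dc_params(x$dc$lambda0, x$dc$mode)
  x$dc <- NULL
  do.call(crunet_config, c(x, list(dc = dc)))
}

# checkpoints: parameter values + config, reconstructable into a network
#' Save / load a trained network
#'
#' A checkpoint stores the configuration and a named list of parameter
#' arrays; `load_checkpoint()` rebuilds the network and fills in the
#' weights.
#'
#' @param net a [build_network()] object.
#' @param path file path.
#' @param extra optional named list stored alongside (training state).
#' @export
save_checkpoint <- function(net, path, extra = list()) {
  ps <- collect_params(net)
  saveRDS(list(config = net$config,
               values = lapply(ps, function(p) p$value),
               extra = extra), path, version = 3)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint`: list with `net` and `extra`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- build_network(ck$config)
  ps <- collect_params(net)
  if (!setequal(names(ps), names(ck$values)))
    stop("checkpoint parameters do not match the configuration")
  for (nm in names(ps)) ps[[nm]]$value <- ck$values[[nm]]
  list(net = net, extra = ck$extra)
}
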