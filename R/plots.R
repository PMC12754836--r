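# Figure helpers. These are presentation plumbing only; metric computation
# never passes through them.

.gg_ok <- function() requireNamespace("ggplot2", quietly = TRUE)

.raster_df <- function(m) {
  data.frame(row = rep(seq_len(nrow(m)), ncol(m)),
             col = rep(seq_len(ncol(m)), each = nrow(m)),
             value = as.numeric(m))
}

#' Display one frame of a cine sequence
#'
#' @param img `(T, H, W)` complex or magnitude array.
#' @param frame frame index.
#' @param crop_quarters drop the top and bottom quarters of the rows to
#'   focus on the central region (display only).
#' @return a ggplot object.
#' @export
plot_cine_frame <- function(img, frame = 1L, crop_quarters = FALSE) {
  if (!.gg_ok()) stop("ggplot2 is required for plotting")
  m <- .as_mag(img)[frame, , ]
  if (crop_quarters) {
    H <- nrow(m)
    m <- m[seq.int(H %/% 4 + 1L, H - H %/% 4), ]
  }
  df <- .raster_df(m)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "|I|", title = sprintf("frame %d", frame)) +
    ggplot2::theme_minimal()
}

#' Error map between a reconstruction and the reference
#'
#' @param rec,gnd `(T, H, W)` arrays.
#' @inheritParams plot_cine_frame
#' @export
plot_error_map <- function(rec, gnd, frame = 1L) {
  if (!.gg_ok()) stop("ggplot2 is required for plotting")
  m <- abs(.as_mag(rec)[frame, , ] - .as_mag(gnd)[frame, , ])
  df <- .raster_df(m)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "|error|") +
    ggplot2::theme_minimal()
}

#' Spatio-temporal (x-t) profile along the central column
#'
#' Shows how a single image line evolves over the cine cycle; motion
#' appears as periodic undulation.
#'
#' @param img `(T, H, W)` array.
#' @param col column index (default: center).
#' @export
plot_xt_profile <- function(img, col = NULL) {
  if (!.gg_ok()) stop("ggplot2 is required for plotting")
  m <- .as_mag(img)
  if (is.null(col)) col <- dim(m)[3] %/% 2L
  xt <- t(m[, , col])   # H x T
  df <- .raster_df(xt)
  names(df) <- c("row", "frame", "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(fill = "|I|", x = "frame", y = "row") +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' @param history the `history` data.frame from [train_model()].
#' @export
plot_training_history <- function(history) {
  if (!.gg_ok()) stop("ggplot2 is required for plotting")
  ggplot2::ggplot(history, ggplot2::aes(.data$epoch, .data$train_loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean training loss") +
    ggplot2::theme_minimal()
}
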