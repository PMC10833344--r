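# ggplot2 display helpers.

#' Display a diffraction image
#'
#' Raster display of a raw or conditioned image in square-root-photon
#' shading (raw counts are square-root compressed for display; conditioned
#' quadrants are already in square-root units). Masked pixels (-1) are
#' shown as missing.
#'
#' @param image A numeric matrix, a `labeled_image` or a
#'   `conditioned_quadrant`.
#' @param compress Square-root compress values for display (default `TRUE`
#'   for plain matrices and labeled images, `FALSE` for conditioned
#'   quadrants).
#' @return A ggplot object.
#' @export
plot_image <- function(image, compress = NULL) {
  if (inherits(image, "labeled_image")) image <- image$pixels
  if (inherits(image, "conditioned_quadrant")) {
    if (is.null(compress)) compress <- FALSE
    image <- image$pixels
  }
  if (is.null(compress)) compress <- TRUE
  v <- image
  v[v < 0] <- NA
  if (compress) v <- sqrt(v)
  df <- tidyr::expand_grid(slow = seq_len(nrow(v)), fast = seq_len(ncol(v)))
  df$value <- v[cbind(df$slow, df$fast)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fast, y = .data$slow,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "red") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "fast (px)", y = "slow (px)", fill = "sqrt counts")
}

#' Training curves of a fit
#'
#' Loss and accuracy per epoch for the training and held-out splits, with
#' the checkpointed epoch marked.
#'
#' @param object A `braggnet_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.braggnet_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = c("split", "metric"), names_sep = "_")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(y = NULL, color = NULL)
}

#' Per-image series of an inference report
#'
#' Resolution (min/mean across quadrants) or overlap probability versus
#' image number, the monitoring-style view of a data set.
#'
#' @param report An [infer_image_set()] tibble.
#' @return A ggplot object.
#' @export
plot_report <- function(report) {
  if (!all(is.na(report$d_min_A))) {
    long <- tidyr::pivot_longer(report, c("d_min_A", "d_mean_A"),
                                names_to = "aggregate", values_to = "d")
    ggplot2::ggplot(long, ggplot2::aes(x = .data$image_id, y = .data$d,
                                       color = .data$aggregate)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::scale_y_reverse() +
      ggplot2::labs(x = "image", y = "resolution (A)", color = NULL)
  } else {
    ggplot2::ggplot(report, ggplot2::aes(x = .data$image_id,
                                         y = .data$p_overlap)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
      ggplot2::labs(x = "image", y = "overlap probability")
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
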