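# Inference over conditioned quadrants, aggregation and data-set summaries.

#' Infer quality metrics for one image
#'
#' Runs the model once per requested quadrant and aggregates. For the
#' resolution head the per-quadrant inverse resolutions are aggregated as
#' `d_min` (the best resolution, i.e. the maximum inverse resolution) and
#' `d_mean` (the mean taken in inverse units and then inverted, the model's
#' native space); `B_min` is derived from `d_min` through the trend. For
#' the overlap head the per-quadrant probabilities are averaged into
#' `p_overlap` and thresholded with [classify_overlap()].
#'
#' With `n_quadrants = 1` only the fit's training quadrant (first in the
#' fixed UL, UR, LL, LR order) is evaluated, and its value equals the first
#' per-quadrant value of the 4-quadrant pass.
#'
#' @param fit A `braggnet_fit` checkpoint.
#' @param quadrants List of `conditioned_quadrant`s from
#'   [condition_image()] (length 4, or 1 when `n_quadrants = 1`).
#' @param geometry The image's [geometry_context()].
#' @param n_quadrants 1 or 4.
#' @param image_id Identifier carried into the record.
#' @param trend [trend_model()] used to derive `B_min`.
#' @param threshold Overlap decision threshold.
#' @return A one-row tibble: `image_id`, `q1`..`q4`, `d_min_A`, `d_mean_A`,
#'   `B_min_A2`, `p_overlap`, `overlap_label` (columns not applicable to
#'   the head are `NA`).
#' @export
infer_image <- function(fit, quadrants, geometry, n_quadrants = 4L,
                        image_id = 1L, trend = trend_model(),
                        threshold = 0.5) {
  stopifnot(inherits(fit, "braggnet_fit"),
            inherits(geometry, "geometry_context"),
            n_quadrants %in% c(1L, 4L))
  order_ids <- c(fit$quadrant, setdiff(c("UL", "UR", "LL", "LR"), fit$quadrant))
  ids <- vapply(quadrants, function(q) q$quadrant_id, character(1))
  use_ids <- order_ids[seq_len(n_quadrants)]
  if (!all(use_ids %in% ids)) {
    stop("quadrants ", paste(setdiff(use_ids, ids), collapse = ", "),
         " are required but missing", call. = FALSE)
  }
  qs <- quadrants[match(use_ids, ids)]
  feats <- do.call(rbind, lapply(qs, quadrant_features, n_shells = fit$n_shells))
  geom <- tibble::tibble(
    wavelength = geometry$beam$wavelength,
    pixel_eff_mm = geometry$detector$pixel_mm * geometry$detector$downsample,
    distance_mm = geometry$distance_mm)[rep(1L, nrow(feats)), ]
  vals <- fit_predict(fit, feats, geom)
  qvals <- rep(NA_real_, 4L)
  qvals[seq_len(n_quadrants)] <- vals

  if (fit$spec$head == "geometry_resolution") {
    agg <- aggregate_quadrant_resolutions(vals)
    d_min <- agg[["d_min"]]
    d_mean <- agg[["d_mean"]]
    tibble::tibble(
      image_id = image_id, q1 = qvals[1], q2 = qvals[2], q3 = qvals[3],
      q4 = qvals[4], d_min_A = d_min, d_mean_A = d_mean,
      B_min_A2 = b_from_resolution(d_min, trend, quiet = TRUE),
      p_overlap = NA_real_, overlap_label = NA)
  } else {
    p <- mean(vals)
    tibble::tibble(
      image_id = image_id, q1 = qvals[1], q2 = qvals[2], q3 = qvals[3],
      q4 = qvals[4], d_min_A = NA_real_, d_mean_A = NA_real_,
      B_min_A2 = NA_real_, p_overlap = p,
      overlap_label = classify_overlap(p, threshold))
  }
}

#' Inference report over an image set
#'
#' Conditions every image of an `image_set` and applies [infer_image()],
#' returning one record per image.
#'
#' @param fit A `braggnet_fit`.
#' @param image_set An `image_set`.
#' @param n_quadrants 1 or 4.
#' @param trend,threshold Passed to [infer_image()].
#' @return A tibble with the [infer_image()] columns, one row per image.
#' @export
infer_image_set <- function(fit, image_set, n_quadrants = 4L,
                            trend = trend_model(), threshold = 0.5) {
  stopifnot(inherits(image_set, "image_set"))
  out <- vector("list", length(image_set$images))
  for (i in seq_along(image_set$images)) {
    ctx <- image_set$geometries[[i]]
    qs <- condition_image(image_set$images[[i]], ctx, quadrants = 4L)
    out[[i]] <- infer_image(fit, qs, ctx, n_quadrants = n_quadrants,
                            image_id = i, trend = trend,
                            threshold = threshold)
  }
  dplyr::bind_rows(out)
}

#' Overlap decision from a probability
#'
#' An image is labeled overlapped when its overlap probability reaches the
#' threshold; probabilities below it mark single-lattice images.
#'
#' @param p Overlap probability (or probabilities) in `[0, 1]`.
#' @param threshold Decision threshold, default 0.5.
#' @return Logical vector: `TRUE` = overlapping lattices.
#' @export
classify_overlap <- function(p, threshold = 0.5) {
  if (any(p < 0 | p > 1)) {
    stop("overlap probability must lie in [0, 1]", call. = FALSE)
  }
  p >= threshold
}

#' Sort records by a key and split into near-equal groups
#'
#' Stable ascending sort followed by a split into `n_groups` contiguous
#' groups whose sizes differ by at most one (any remainder goes to the
#' earlier groups). Used e.g. to split an image set into halves by overlap
#' probability or into high/mid/low resolution tiers.
#'
#' @param records A data frame of per-image records.
#' @param key Column name to sort by (default `"p_overlap"`).
#' @param n_groups Number of groups.
#' @return The records sorted by `key` with an integer `group` column
#'   prepended; the key values at the group boundaries are attached as the
#'   `"boundaries"` attribute (a tibble with `group`, `lo`, `hi`).
#' @export
sort_and_split <- function(records, key = "p_overlap", n_groups = 2L) {
  records <- tibble::as_tibble(records)
  n <- nrow(records)
  if (n == 0L) stop("no records to split", call. = FALSE)
  n_groups <- as.integer(n_groups)
  if (n_groups < 1L || n_groups > n) {
    stop("need at least as many records as groups", call. = FALSE)
  }
  ord <- order(records[[key]])  # stable (radix/merge) in base R
  sorted <- records[ord, , drop = FALSE]
  base <- n %/% n_groups
  sizes <- base + (seq_len(n_groups) <= n %% n_groups)
  grp <- rep.int(seq_len(n_groups), sizes)
  out <- dplyr::bind_cols(tibble::tibble(group = grp), sorted)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  attr(out, "boundaries") <- tibble::tibble(
    group = seq_len(n_groups),
    lo = sorted[[key]][starts], hi = sorted[[key]][ends])
  out
}

#' Summarize an inference report over a data set
#'
#' Arithmetic means over images: the bracketed quantities `<B_min>` and
#' `<d_min>` (and `<d_mean>`), plus the fraction of images labeled as
#' containing overlapping lattices.
#'
#' @param records An [infer_image_set()] report (rows may mix heads; `NA`
#'   columns are skipped with `na.rm`).
#' @return A one-row tibble: `n_images`, `B_min_mean_A2`, `d_min_mean_A`,
#'   `d_mean_mean_A`, `overlap_fraction`.
#' @export
summarize_dataset <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) stop("no records to summarize", call. = FALSE)
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  tibble::tibble(
    n_images = nrow(records),
    B_min_mean_A2 = mean_or_na(records$B_min_A2),
    d_min_mean_A = mean_or_na(records$d_min_A),
    d_mean_mean_A = mean_or_na(records$d_mean_A),
    overlap_fraction = if (all(is.na(records$overlap_label))) NA_real_ else
      mean(records$overlap_label, na.rm = TRUE))
}
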