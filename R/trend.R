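#' B-factor / resolution trend
#'
#' The monotone quadratic relationship `B(d) = a d^2 + b d + c` (B in
#' Angstrom^2, d in Angstrom) between the overall Debye-Waller B factor of a
#' deposited structure and its resolution. The trend is used in two
#' directions: to choose a B factor that realizes a target resolution when
#' simulating labeled images, and to convert an inferred B factor back to a
#' resolution. The shipped default `(a, b, c) = (4, 0, 12)` is the classic
#' rule-of-thumb `B = 4 d^2 + 12`; any other quadratic can be supplied or
#' refit from a `(d, mean B)` summary table with [fit_trend()].
#'
#' The trend is considered calibrated on `fit_range` (default 1-4.5 Angstrom)
#' and unreliable beyond `reliable_limit` (default 5.5 Angstrom): conversions
#' outside the range warn or flag, they never clamp unless asked to.
#'
#' @param a,b,c Quadratic coefficients.
#' @param fit_range Length-2 numeric, the resolution interval (Angstrom) on
#'   which the trend is calibrated.
#' @param reliable_limit Resolutions above this (Angstrom) are flagged as
#'   low-confidence when inverting.
#'
#' @return An object of class `trend_model`.
#' @export
trend_model <- function(a = 4, b = 0, c = 12, fit_range = c(1, 4.5),
                        reliable_limit = 5.5) {
  stopifnot(length(fit_range) == 2L, fit_range[1] < fit_range[2])
  tm <- structure(
    list(a = a, b = b, c = c, fit_range = as.numeric(fit_range),
         reliable_limit = reliable_limit),
    class = "trend_model")
  # strict monotonicity where the trend is calibrated: derivative 2ad + b > 0
  # on [d_lo, d_hi] (a refit from noisy summaries may carry a tiny negative
  # linear term whose effect below d_lo is irrelevant to either direction
  # of use)
  dgrid <- seq(fit_range[1], fit_range[2], length.out = 256L)
  if (any(2 * a * dgrid + b <= 0)) {
    stop("invalid trend: B(d) must be strictly increasing on (0, d_hi]",
         call. = FALSE)
  }
  tm
}

#' B factor realizing a resolution under a trend
#'
#' @param d Resolution(s), Angstrom; must be positive.
#' @param trend A [trend_model()].
#' @param quiet Suppress the out-of-range warning.
#' @return B factor(s), Angstrom^2.
#' @export
b_from_resolution <- function(d, trend = trend_model(), quiet = FALSE) {
  stopifnot(inherits(trend, "trend_model"))
  if (any(d <= 0)) stop("resolution must be positive", call. = FALSE)
  if (!quiet && any(d < trend$fit_range[1] | d > trend$fit_range[2])) {
    warning("resolution outside the trend's calibrated range [",
            trend$fit_range[1], ", ", trend$fit_range[2], "] Angstrom",
            call. = FALSE)
  }
  trend$a * d^2 + trend$b * d + trend$c
}

#' Resolution realizing a B factor under a trend
#'
#' Inverts the quadratic: the unique positive root of
#' `a d^2 + b d + (c - B) = 0`. Values above the trend's `reliable_limit`
#' are flagged through the `"low_confidence"` attribute (and optionally
#' clamped), mirroring the caveat that the trend is unreliable at low
#' resolution.
#'
#' @param B B factor(s), Angstrom^2. Must be at least the trend's value at
#'   `d -> 0+` (i.e. `c`).
#' @param trend A [trend_model()].
#' @param clamp Clamp results at `reliable_limit` instead of only flagging?
#' @return Resolution(s) in Angstrom with a logical attribute
#'   `"low_confidence"` marking values beyond the reliable limit.
#' @export
resolution_from_b <- function(B, trend = trend_model(), clamp = FALSE) {
  stopifnot(inherits(trend, "trend_model"))
  if (any(B < trend$c)) {
    stop("B below the trend's minimum (", trend$c, " Angstrom^2): no positive root",
         call. = FALSE)
  }
  a <- trend$a; b <- trend$b
  if (a == 0) {
    d <- (B - trend$c) / b
  } else {
    disc <- b^2 + 4 * a * (B - trend$c)
    d <- (-b + sqrt(disc)) / (2 * a)
  }
  low <- d > trend$reliable_limit
  if (clamp) d[low] <- trend$reliable_limit
  attr(d, "low_confidence") <- low
  d
}

#' Fit a quadratic trend to (resolution, mean B) summary points
#'
#' Ordinary least squares on the points falling inside `range`; points
#' outside are ignored, so adding out-of-range outliers leaves the
#' coefficients unchanged.
#'
#' @param points A data frame with columns `d` (Angstrom) and `B`
#'   (Angstrom^2), or a two-column numeric object coercible to one. A path to
#'   a two-column whitespace/comma-delimited text file is also accepted.
#' @param range Length-2 resolution interval to fit on (default 1-4.5).
#' @param reliable_limit Stored on the returned model (default 5.5).
#' @return A [trend_model()] with a `fit` attribute holding the underlying
#'   `lm` object.
#' @export
fit_trend <- function(points, range = c(1, 4.5), reliable_limit = 5.5) {
  if (is.character(points) && length(points) == 1L) {
    points <- utils::read.table(points, header = FALSE,
                                col.names = c("d", "B"))
  }
  points <- as.data.frame(points)
  if (!all(c("d", "B") %in% names(points))) {
    names(points)[1:2] <- c("d", "B")
  }
  use <- points$d >= range[1] & points$d <= range[2]
  if (sum(use) < 3L) {
    stop("insufficient data: need at least 3 points inside the fit range",
         call. = FALSE)
  }
  fit <- stats::lm(B ~ d + I(d^2), data = points[use, , drop = FALSE])
  cf <- stats::coef(fit)
  tm <- tryCatch(
    trend_model(a = unname(cf[["I(d^2)"]]), b = unname(cf[["d"]]),
                c = unname(cf[["(Intercept)"]]),
                fit_range = range, reliable_limit = reliable_limit),
    error = function(e) stop("invalid trend: fitted quadratic is not monotone ",
                             "increasing on the fit range", call. = FALSE))
  attr(tm, "fit") <- fit
  tm
}

#' @export
print.trend_model <- function(x, ...) {
  cat(sprintf("<trend_model> B(d) = %.4g d^2 + %.4g d + %.4g\n", x$a, x$b, x$c))
  cat(sprintf("  calibrated on [%.3g, %.3g] A; unreliable beyond %.3g A\n",
              x$fit_range[1], x$fit_range[2], x$reliable_limit))
  invisible(x)
}

#' Tidy a trend model
#'
#' @param x A [trend_model()].
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`term`, `estimate`, and
#'   `std.error` when the model was produced by [fit_trend()]).
#' @export
tidy.trend_model <- function(x, ...) {
  out <- tibble::tibble(
    term = c("d^2", "d", "intercept"),
    estimate = c(x$a, x$b, x$c))
  fit <- attr(x, "fit")
  if (!is.null(fit)) {
    se <- summary(fit)$coefficients[, "Std. Error"]
    out$std.error <- unname(se[c("I(d^2)", "d", "(Intercept)")])
  }
  out
}

#' @rdname tidy.trend_model
#' @return `glance()` returns a one-row tibble with the fit range, the
#'   reliable limit and (for fitted trends) `r.squared` and `nobs`.
#' @export
glance.trend_model <- function(x, ...) {
  out <- tibble::tibble(
    d_lo = x$fit_range[1], d_hi = x$fit_range[2],
    reliable_limit = x$reliable_limit)
  fit <- attr(x, "fit")
  if (!is.null(fit)) {
    s <- summary(fit)
    out$r.squared <- s$r.squared
    out$nobs <- length(fit$residuals)
  }
  out
}
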