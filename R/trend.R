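# Synthetic pseudo-proxy record generation and least-squares secular trend
# regression (raw and binned), mirroring how carbonate carbon-isotope
# compilations are screened for long-term drift.

#' Generate a synthetic pseudo-proxy series
#'
#' Scattered-age records with a configurable linear secular trend, Gaussian
#' noise and optional boxcar excursions, emulating the structure of isotope
#' compilations (irregular sampling, superimposed excursions). The generator
#' records its own ground truth in attributes for recovery tests.
#'
#' @param kind One of `"d13C"`, `"d34S"`, `"sr"` (a label only).
#' @param n_points Number of records (>= 2).
#' @param age_span Length-2 ages, Ma (old, young in any order).
#' @param intercept Value at the old end of the span.
#' @param trend_per_Myr Change per Myr towards the present (positive =
#'   values increase towards the present).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param excursions List of `list(start, end, amplitude)` boxcar excursions
#'   (ages in Ma).
#' @param seed Optional integer seed.
#' @return Data frame of class `proxy_series` with columns `age_Ma`,
#'   `value`; attributes `kind` and `ground_truth`.
#' @export
synthesize_proxy_series <- function(kind = c("d13C", "d34S", "sr"),
                                    n_points = 500,
                                    age_span = c(1000, 541),
                                    intercept = 2, trend_per_Myr = 0,
                                    noise_sd = 1, excursions = list(),
                                    seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(n_points >= 2, noise_sd >= 0, length(age_span) == 2)
  if (age_span[1] == age_span[2]) stop("invalid age span")
  if (!is.null(seed)) set.seed(seed)
  old <- max(age_span); young <- min(age_span)
  ages <- stats::runif(n_points, young, old)
  values <- intercept + trend_per_Myr * (old - ages) +
    stats::rnorm(n_points, 0, noise_sd)
  for (ex in excursions) {
    sel <- ages <= max(ex$start, ex$end) & ages >= min(ex$start, ex$end)
    values[sel] <- values[sel] + ex$amplitude
  }
  out <- data.frame(age_Ma = ages, value = values)
  attr(out, "kind") <- kind
  attr(out, "ground_truth") <- list(
    intercept = intercept, trend_per_Myr = trend_per_Myr,
    noise_sd = noise_sd, age_span = c(old, young),
    total_change = trend_per_Myr * (old - young), excursions = excursions
  )
  class(out) <- c("proxy_series", "data.frame")
  out
}

#' Bin a proxy series into fixed-width age groups
#'
#' Bins are anchored at the oldest age of the series; each non-empty bin
#' contributes its midpoint age and unweighted mean value. Empty bins are
#' dropped.
#'
#' @param series Data frame with `age_Ma` and `value`.
#' @param width_Myr Bin width (> 0).
#' @return Data frame: `age_Ma` (bin midpoints), `value` (bin means),
#'   `n` (records per bin).
#' @export
bin_series <- function(series, width_Myr) {
  stopifnot(width_Myr > 0)
  if (nrow(series) == 0) stop("bin_series: empty input")
  old <- max(series$age_Ma)
  idx <- floor((old - series$age_Ma) / width_Myr)
  agg_v <- tapply(series$value, idx, mean)
  agg_n <- tapply(series$value, idx, length)
  k <- as.numeric(names(agg_v))
  out <- data.frame(age_Ma = old - (k + 0.5) * width_Myr,
                    value = as.numeric(agg_v), n = as.numeric(agg_n))
  out[order(out$age_Ma, decreasing = TRUE), ]
}

#' Least-squares secular trend of a proxy series
#'
#' Ordinary least squares of value on age. The reported slope uses the
#' towards-the-present sign convention: positive slope means values increase
#' as age decreases. The p-value is the two-sided t-test on the slope.
#'
#' @param series Data frame with `age_Ma` and `value` (>= 3 points, >= 2
#'   distinct ages).
#' @param bin_width_Myr Optional bin width; if > 0 the series is binned with
#'   [bin_series()] before fitting (0 = raw).
#' @return List of class `trend_fit`: slope and intercept (towards-present
#'   convention), `slope_se`, `p_value`, `ci95` (length-2), `n`,
#'   `bin_width_Myr`, `span_Myr` and `total_change` (= slope x span).
#' @export
fit_trend <- function(series, bin_width_Myr = 0) {
  if (bin_width_Myr > 0) series <- bin_series(series, bin_width_Myr)
  if (nrow(series) < 3) stop("fit_trend: need at least 3 points")
  if (length(unique(series$age_Ma)) < 2) stop("fit_trend: degenerate ages")
  fit <- stats::lm(value ~ age_Ma, data = series)
  sm <- summary(fit)$coefficients
  slope_age <- sm["age_Ma", "Estimate"]
  se <- sm["age_Ma", "Std. Error"]
  p <- sm["age_Ma", "Pr(>|t|)"]
  ci <- stats::confint(fit)["age_Ma", ]
  span <- max(series$age_Ma) - min(series$age_Ma)
  structure(
    list(slope = -slope_age, intercept = unname(stats::coef(fit)[1]),
         slope_se = se, p_value = p,
         ci95 = sort(-unname(ci)), n = nrow(series),
         bin_width_Myr = bin_width_Myr, span_Myr = span,
         total_change = -slope_age * span),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> slope %.4g /Myr (towards present), se %.3g, p = %.3g\n",
    x$slope, x$slope_se, x$p_value))
  cat(sprintf("  n = %d, bin width %g Myr, total change %.3g over %g Myr\n",
              x$n, x$bin_width_Myr, x$total_change, x$span_Myr))
  invisible(x)
}

#' Read / write proxy series tables
#'
#' Plain CSV with columns `age_Ma`, `value`.
#' @param path File path.
#' @param series Data frame with `age_Ma`, `value`.
#' @return `read_proxy_csv` returns a data frame.
#' @export
read_proxy_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("age_Ma", "value") %in% names(d)))
  d
}

#' @rdname read_proxy_csv
#' @export
write_proxy_csv <- function(series, path) {
  utils::write.csv(series[, c("age_Ma", "value")], path, row.names = FALSE)
  invisible(path)
}
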