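#' Cleavage ratio of a substrate-cleavage immunoblot
#'
#' `product / (substrate + product)`: the fraction of substrate converted
#' to cleavage product, computed from band intensities. Scale-invariant and
#' bounded in \[0, 1\].
#'
#' @param substrate,product Non-negative band intensities (vectorized).
#' @return Cleavage ratio(s) in \[0, 1\].
#' @examples
#' cleavage_ratio(substrate = 20, product = 80)  # 0.8
#' complex_fraction(monomer = 3, dimer = 1, complex = 1)  # 0.2
#' @export
cleavage_ratio <- function(substrate, product) {
  if (any(substrate < 0 | product < 0)) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  if (any(substrate + product == 0)) {
    stop("substrate + product must be > 0", call. = FALSE)
  }
  product / (substrate + product)
}

#' Cross-linked complex fraction of a cross-linking immunoblot
#'
#' `complex / (monomer + dimer + complex)`: the abundance of the
#' cross-linked enzyme-substrate complex relative to all enzyme species.
#'
#' @param monomer,dimer,complex Non-negative band intensities (vectorized).
#' @return Complex fraction(s) in \[0, 1\].
#' @export
complex_fraction <- function(monomer, dimer, complex) {
  if (any(monomer < 0 | dimer < 0 | complex < 0)) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  tot <- monomer + dimer + complex
  if (any(tot == 0)) stop("total intensity must be > 0", call. = FALSE)
  complex / tot
}

#' Add band ratios to an intensity table
#'
#' Tidy wrappers over [cleavage_ratio()] and [complex_fraction()]:
#' `quantify_cleavage()` expects columns `substrate` and `product`;
#' `quantify_crosslinking()` expects `monomer`, `dimer` and `complex`.
#' Other columns (condition, time, replicate) pass through.
#'
#' @param data A data frame of band intensities.
#' @return The tibble with a `ratio` column appended.
#' @export
quantify_cleavage <- function(data) {
  data <- tibble::as_tibble(data)
  dplyr::mutate(data, ratio = cleavage_ratio(.data$substrate, .data$product))
}

#' @rdname quantify_cleavage
#' @export
quantify_crosslinking <- function(data) {
  data <- tibble::as_tibble(data)
  dplyr::mutate(data, ratio = complex_fraction(.data$monomer, .data$dimer,
                                               .data$complex))
}

#' Fit a linear trend to a ratio time course
#'
#' Ordinary least squares straight line on the pooled replicate points
#' (replicates are not averaged first), the reading of the "best-fit trend
#' line" drawn through cross-linking time courses.
#'
#' @param data Data frame with the time and ratio columns (one row per
#'   replicate measurement).
#' @param time,ratio Column names (tidy-eval) of time (minutes) and ratio.
#' @return A `trend_fit` object wrapping the [stats::lm()] fit; see
#'   [tidy.trend_fit()], [glance.trend_fit()], [augment.trend_fit()] and
#'   [autoplot.trend_fit()].
#' @export
fit_trend <- function(data, time = time, ratio = ratio) {
  data <- tibble::as_tibble(data)
  df <- tibble::tibble(time = dplyr::pull(data, {{ time }}),
                       ratio = dplyr::pull(data, {{ ratio }}))
  if (dplyr::n_distinct(df$time) < 2) {
    stop("need at least 2 distinct time points", call. = FALSE)
  }
  fit <- stats::lm(ratio ~ time, data = df)
  structure(list(fit = fit, data = df), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  co <- stats::coef(x$fit)
  cat("<trend_fit> ratio = ", format(co[2], digits = 4), " * time + ",
      format(co[1], digits = 4), "  (n = ", nrow(x$data), ")\n", sep = "")
  invisible(x)
}

#' Broom-style methods for trend fits
#'
#' `tidy()` returns the slope and intercept with standard errors;
#' `glance()` the fit summary; `augment()` the data with fitted values and
#' residuals.
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.trend_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = unname(s[, 1]), std_error = unname(s[, 2]),
                 statistic = unname(s[, 3]), p_value = unname(s[, 4]))
}

#' @rdname tidy.trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r_squared = s$r.squared, sigma = s$sigma,
                 n = nrow(x$data))
}

#' @rdname tidy.trend_fit
#' @export
augment.trend_fit <- function(x, ...) {
  dplyr::mutate(x$data, fitted = stats::fitted(x$fit),
                residual = stats::residuals(x$fit))
}

#' Two-tailed t-test between two conditions' ratios
#'
#' Thin convenience around [stats::t.test()] (two-sided, Welch) for
#' comparing band ratios between two condition labels.
#'
#' @param data Data frame with a ratio column and a grouping column with
#'   exactly two levels among those selected.
#' @param ratio,group Column names (tidy-eval).
#' @return One-row tibble: group means, difference, t statistic, df,
#'   p value.
#' @export
compare_ratios <- function(data, ratio = ratio, group = condition) {
  data <- tibble::as_tibble(data)
  v <- dplyr::pull(data, {{ ratio }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  lv <- unique(g)
  if (length(lv) != 2) stop("need exactly 2 groups", call. = FALSE)
  tt <- stats::t.test(v[g == lv[1]], v[g == lv[2]], alternative = "two.sided")
  tibble::tibble(group_1 = lv[1], group_2 = lv[2],
                 mean_1 = mean(v[g == lv[1]]), mean_2 = mean(v[g == lv[2]]),
                 difference = mean(v[g == lv[1]]) - mean(v[g == lv[2]]),
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value)
}
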