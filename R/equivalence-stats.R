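#' Summary triple feeding the equivalence confidence intervals
#'
#' @param mean Arithmetic mean of the batch parameter.
#' @param sd Sample standard deviation (same units).
#' @param n Number of observations (>= 2).
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  stopifnot(length(mean) == 1L, length(sd) == 1L, length(n) == 1L)
  if (!is.finite(mean) || !is.finite(sd) || sd < 0)
    stop("group_summary: mean must be finite and sd non-negative")
  if (n < 2) stop("group_summary: n must be at least 2")
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd), n = as.integer(n)),
            class = "group_summary")
}

#' @rdname group_summary
#' @param x Numeric vector of raw replicate values.
#' @export
summarize_group <- function(x) {
  x <- x[is.finite(x)]
  group_summary(mean(x), stats::sd(x), length(x))
}

new_ci_result <- function(point, lower, upper, df, alpha, scale) {
  structure(list(point = point, lower = lower, upper = upper,
                 df = df, alpha = alpha, scale = scale),
            class = "ci_result")
}

#' @export
print.ci_result <- function(x, ...) {
  cat(sprintf("%d%% CI (%s): point %.4f, [%.4f, %.4f], df = %.2f\n",
              round(100 * (1 - x$alpha)), x$scale, x$point, x$lower, x$upper, x$df))
  invisible(x)
}

welch_df <- function(test, ref) {
  a <- test$sd^2 / test$n
  b <- ref$sd^2 / ref$n
  if (a + b == 0) return(test$n + ref$n - 2)  # degenerate: fall back to pooled
  (a + b)^2 / (a^2 / (test$n - 1) + b^2 / (ref$n - 1))
}

#' 90% confidence interval of the difference of batch means
#'
#' Two-sample interval `(Xbar_test - Xbar_ref) +/- t_{1-alpha/2, df} *
#' sqrt(s_t^2/n_t + s_r^2/n_r)`, the construction the EMA draft guideline
#' prescribes for quantitative physicochemical parameters. Degrees of
#' freedom follow Welch--Satterthwaite by default; the pooled-variance rule
#' is available for sensitivity analyses.
#'
#' @param test,ref [group_summary()] objects for the two arms.
#' @param alpha Two-sided error rate; 0.10 gives the guideline 90% CI.
#' @param df_rule `"welch"` (default) or `"pooled"`.
#' @return A `ci_result` on the difference scale.
#' @export
ci_difference <- function(test, ref, alpha = 0.10, df_rule = c("welch", "pooled")) {
  stopifnot(inherits(test, "group_summary"), inherits(ref, "group_summary"))
  df_rule <- match.arg(df_rule)
  df <- if (df_rule == "welch") welch_df(test, ref) else test$n + ref$n - 2
  se <- sqrt(test$sd^2 / test$n + ref$sd^2 / ref$n)
  tq <- stats::qt(1 - alpha / 2, df)
  point <- test$mean - ref$mean
  new_ci_result(point, point - tq * se, point + tq * se, df, alpha, "difference")
}

#' 90% confidence interval of the ratio of batch means
#'
#' Ratio-scale interval for release and physicochemical parameters:
#' `Xbar_test/Xbar_ref +/- t_{1-alpha/2, df} * SE / Xbar_ref`, i.e. the
#' two-sample difference interval shifted by the reference mean and divided
#' by it, which keeps the interval dimensionless. This reading reproduces
#' the guideline-style discriminatory-power intervals exactly from printed
#' batch summaries.
#'
#' @inheritParams ci_difference
#' @return A `ci_result` on the ratio scale.
#' @examples
#' ci_ratio(group_summary(70.91, 2.92, 12), group_summary(60.13, 3.48, 12))
#' @export
ci_ratio <- function(test, ref, alpha = 0.10, df_rule = c("welch", "pooled")) {
  stopifnot(inherits(ref, "group_summary"))
  if (ref$mean == 0) stop("ci_ratio: reference mean is zero")
  d <- ci_difference(test, ref, alpha = alpha, df_rule = df_rule)
  # exact shift-and-scale of the difference CI: guarantees the algebraic
  # identity between the two interval engines
  new_ci_result((ref$mean + d$point) / ref$mean,
                (ref$mean + d$lower) / ref$mean,
                (ref$mean + d$upper) / ref$mean,
                d$df, alpha, "ratio")
}

#' Log-scale ratio confidence interval from raw positive values
#'
#' The standard bioequivalence construction for skin-permeation parameters:
#' a two-sample Welch interval on log-transformed values, exponentiated to
#' the ratio scale. The point estimate is the ratio of geometric means.
#'
#' @param test,ref Numeric vectors of positive values (e.g. per-donor
#'   geometric means of flux or Q24h).
#' @param alpha Two-sided error rate (default 0.10).
#' @return A `ci_result` on the ratio scale.
#' @export
ci_ratio_log <- function(test, ref, alpha = 0.10) {
  if (any(test <= 0) || any(ref <= 0))
    stop("ci_ratio_log: all values must be positive for log transformation")
  d <- ci_difference(summarize_group(log(test)), summarize_group(log(ref)),
                     alpha = alpha, df_rule = "welch")
  new_ci_result(exp(d$point), exp(d$lower), exp(d$upper), d$df, alpha, "ratio")
}

#' Guideline acceptance ranges
#'
#' Closed ratio-scale ranges: 90--110% for quantitative physicochemical /
#' microstructure parameters, 90--111% for IVRT release parameters,
#' 80--125% for IVPT permeation parameters.
#'
#' @return Named list of `c(lo, hi)` ranges.
#' @export
equivalence_ranges <- function() {
  list(physchem_90_110 = c(0.90, 1.10),
       ivrt_90_111     = c(0.90, 1.11),
       ivpt_80_125     = c(0.80, 1.25))
}

#' Position of a confidence interval relative to an acceptance range
#'
#' `within` if the whole interval lies inside the closed range (equivalence
#' claimable), `outside` if the whole interval lies beyond it (full
#' discrimination), `straddles` otherwise.
#'
#' @param ci A ratio-scale `ci_result`.
#' @param range_name One of `names(equivalence_ranges())`.
#' @return An object of class `equivalence_verdict` with fields
#'   `range_name`, `range` and `status`.
#' @export
range_check <- function(ci, range_name) {
  stopifnot(inherits(ci, "ci_result"))
  ranges <- equivalence_ranges()
  if (!range_name %in% names(ranges))
    stop("range_check: unknown acceptance range '", range_name,
         "'; registered: ", paste(names(ranges), collapse = ", "))
  r <- ranges[[range_name]]
  status <-
    if (ci$lower >= r[1] && ci$upper <= r[2]) "within"
    else if (ci$upper < r[1] || ci$lower > r[2]) "outside"
    else "straddles"
  structure(list(range_name = range_name, range = r, status = status,
                 lower = ci$lower, upper = ci$upper),
            class = "equivalence_verdict")
}

#' @export
print.equivalence_verdict <- function(x, ...) {
  cat(sprintf("CI [%.4f, %.4f] vs %s [%g, %g]: %s\n",
              x$lower, x$upper, x$range_name, x$range[1], x$range[2], x$status))
  invisible(x)
}

#' Nonparametric bootstrap ratio interval
#'
#' Percentile 90% interval of a ratio statistic over paired nonparametric
#' resamples of the two arms; a resampling alternative for small-sample
#' studies where the t-based intervals are considered too dependent on n.
#'
#' @param test,ref Numeric vectors of raw values.
#' @param statistic `"ratio_of_means"` or `"ratio_of_geomeans"`.
#' @param reps Number of bootstrap resamples (>= 1000).
#' @param seed Mandatory RNG seed for reproducibility.
#' @param alpha Two-sided error rate (default 0.10).
#' @return A `ci_result` (df is `NA` for resampling intervals).
#' @export
bootstrap_ci <- function(test, ref,
                         statistic = c("ratio_of_means", "ratio_of_geomeans"),
                         reps = 5000, seed, alpha = 0.10) {
  statistic <- match.arg(statistic)
  if (missing(seed)) stop("bootstrap_ci: a seed is required")
  if (reps < 1000) stop("bootstrap_ci: reps must be at least 1000")
  if (!length(test) || !length(ref)) stop("bootstrap_ci: empty arm")
  stat_fun <- if (statistic == "ratio_of_means") {
    function(a, b) mean(a) / mean(b)
  } else {
    function(a, b) exp(mean(log(a)) - mean(log(b)))
  }
  if (statistic == "ratio_of_geomeans" && (any(test <= 0) || any(ref <= 0)))
    stop("bootstrap_ci: geometric-mean statistic requires positive values")
  set.seed(seed)
  draws <- vapply(seq_len(reps), function(i) {
    stat_fun(sample(test, replace = TRUE), sample(ref, replace = TRUE))
  }, numeric(1))
  qs <- stats::quantile(draws, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  new_ci_result(stat_fun(test, ref), qs[1], qs[2], NA_real_, alpha, "ratio")
}

#' Relative standard deviation in percent
#'
#' @param x Numeric vector.
#' @return `100 * sd(x) / mean(x)`.
#' @export
cv_pct <- function(x) {
  m <- mean(x)
  if (m == 0) stop("cv_pct: mean is zero, CV undefined")
  100 * stats::sd(x) / m
}
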