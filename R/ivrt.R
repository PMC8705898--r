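# R^2 with a guard for (numerically) constant responses, where summary.lm's
# ratio of round-off terms is meaningless; zero variance explained -> 0.
ols_r2 <- function(y, fitted) {
  tss <- sum((y - mean(y))^2)
  if (tss <= 1e-20 * length(y) * (1 + mean(y)^2)) return(0)
  max(0, min(1, 1 - sum((y - fitted)^2) / tss))
}

#' Higuchi release-kinetics fit
#'
#' Ordinary least squares of cumulative amount per area on the square root
#' of time. The slope is the release rate constant K (ug h^-1/2 cm^-2); the
#' fit includes an intercept by default, since burst release or a short lag
#' biases forced-through-zero fits. Q6h is the measured (or linearly
#' interpolated) cumulative amount at 6 h, reported independently of the
#' regression line.
#'
#' @param profile A `cumulative_profile`.
#' @param window Optional `c(t_min, t_max)` restricting the fitted points;
#'   default: all points with `t > 0`.
#' @param intercept Include an intercept term (default `TRUE`).
#' @param q_time Time (h) at which the terminal cumulative amount is read
#'   (default 6, the IVRT endpoint).
#' @return An object of class `release_params`: fields `K`, `intercept`,
#'   `r2`, `q6`, `se_K`, `df`, `replicate_id`.
#' @export
higuchi_fit <- function(profile, window = NULL, intercept = TRUE, q_time = 6) {
  stopifnot(inherits(profile, "cumulative_profile"))
  keep <- profile$times_h > 0
  if (!is.null(window))
    keep <- keep & profile$times_h >= window[1] & profile$times_h <= window[2]
  t <- profile$times_h[keep]
  q <- profile$q_ug_cm2[keep]
  if (length(t) < 3)
    stop("higuchi_fit: need at least 3 positive-time points (got ", length(t), ")")
  rt <- sqrt(t)
  if (stats::sd(rt) == 0) stop("higuchi_fit: zero variance in sqrt(time)")
  fit <- if (intercept) stats::lm(q ~ rt) else stats::lm(q ~ rt + 0)
  co <- stats::coef(fit)
  K <- unname(co[["rt"]])
  b0 <- if (intercept) unname(co[["(Intercept)"]]) else 0
  rss <- sum(stats::residuals(fit)^2)
  sxx <- if (intercept) sum((rt - mean(rt))^2) else sum(rt^2)
  se_K <- if (fit$df.residual > 0) sqrt(rss / fit$df.residual / sxx) else NA_real_
  q6 <- if (q_time >= profile$times_h[1] && q_time <= max(profile$times_h))
    interpolate_q(profile, q_time) else NA_real_
  structure(
    list(K = K, intercept = b0, r2 = ols_r2(q, stats::fitted(fit)), q6 = q6,
         se_K = se_K,
         df = fit$df.residual, replicate_id = profile$replicate_id),
    class = "release_params"
  )
}

#' @export
print.release_params <- function(x, ...) {
  cat(sprintf("Higuchi fit [%s]: K = %.3f ug/h^0.5/cm^2, intercept = %.3f, r2 = %.4f, Q6h = %.3f\n",
              x$replicate_id, x$K, x$intercept, x$r2, x$q6))
  invisible(x)
}

#' Tabulate release parameters for a set of profiles
#'
#' @param profiles List of `cumulative_profile` objects.
#' @param ... Passed to [higuchi_fit()].
#' @return data.frame with columns `replicate_id`, `K`, `intercept`, `r2`, `q6`.
#' @export
release_table <- function(profiles, ...) {
  fits <- lapply(profiles, higuchi_fit, ...)
  do.call(rbind, lapply(fits, function(f)
    data.frame(replicate_id = f$replicate_id, K = f$K, intercept = f$intercept,
               r2 = f$r2, q6 = f$q6)))
}

#' IVRT linearity across dose strengths
#'
#' Regresses individual release parameters (K and Q6h) on formulation
#' strength; the method is declared linear when both regression r^2 exceed
#' the 0.90 guideline threshold.
#'
#' @param params data.frame with columns `strength`, `K`, `q6` (one row per
#'   replicate; at least 3 distinct strengths).
#' @param r2_threshold Pass threshold (default 0.90).
#' @return data.frame (one row per parameter) with slope, intercept, r2 and
#'   a `pass` flag.
#' @export
linearity_check <- function(params, r2_threshold = 0.90) {
  stopifnot(all(c("strength", "K", "q6") %in% names(params)))
  if (length(unique(params$strength)) < 3)
    stop("linearity_check: need at least 3 distinct strengths")
  one <- function(y) {
    fit <- stats::lm(y ~ strength, data = params)
    r2 <- ols_r2(y, stats::fitted(fit))
    data.frame(slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r2 = r2, pass = r2 > r2_threshold)
  }
  out <- rbind(one(params$K), one(params$q6))
  out <- cbind(parameter = c("K", "q6"), out)
  rownames(out) <- NULL
  out
}

#' IVRT intermediate precision
#'
#' Relative standard deviation (CV%) of K and Q6h per operator/day group and
#' pooled over all raw replicates; the guideline requires the global CV to
#' stay below 10%.
#'
#' @param params data.frame with columns `operator`, `K`, `q6`.
#' @param cv_threshold Pass threshold in percent (default 10).
#' @return List with `by_group` (data.frame of per-group mean/SD/CV per
#'   parameter), `global` (pooled CVs) and `pass`.
#' @export
intermediate_precision <- function(params, cv_threshold = 10) {
  stopifnot(all(c("operator", "K", "q6") %in% names(params)))
  if (length(unique(params$operator)) < 2)
    stop("intermediate_precision: need at least 2 operator groups")
  per <- do.call(rbind, lapply(split(params, params$operator), function(d) {
    data.frame(operator = d$operator[1],
               K_mean = mean(d$K), K_sd = stats::sd(d$K), K_cv = cv_pct(d$K),
               q6_mean = mean(d$q6), q6_sd = stats::sd(d$q6), q6_cv = cv_pct(d$q6))
  }))
  rownames(per) <- NULL
  glob <- c(K_cv = cv_pct(params$K), q6_cv = cv_pct(params$q6))
  list(by_group = per, global = glob, pass = all(glob < cv_threshold))
}

#' IVRT discriminatory power
#'
#' Ratio CI of a deliberately altered (e.g. reduced-viscosity) formulation
#' against the standard one; the method discriminates only when the whole
#' 90% interval falls outside the 90--111% IVRT range.
#'
#' @param test,ref [group_summary()] of the release parameter in each arm.
#' @param ... Passed to [ci_ratio()].
#' @return List with `ci` (a `ci_result`), `verdict` (an
#'   `equivalence_verdict`) and `discriminates` (logical).
#' @export
discriminatory_power <- function(test, ref, ...) {
  ci <- ci_ratio(test, ref, ...)
  v <- range_check(ci, "ivrt_90_111")
  list(ci = ci, verdict = v, discriminates = v$status == "outside")
}

#' IVRT robustness ANOVA
#'
#' One-way ANOVA of a release parameter between standard-condition runs and
#' runs under one modified operational factor; a factor is flagged when
#' p < 0.05.
#'
#' @param standard,modified data.frames with columns `K`, `q6` (>= 2 rows each).
#' @param alpha Significance threshold (default 0.05).
#' @return data.frame (per parameter) with group means, p-value and
#'   `significant` flag.
#' @export
robustness_anova <- function(standard, modified, alpha = 0.05) {
  stopifnot(nrow(standard) >= 2, nrow(modified) >= 2)
  one <- function(par) {
    y <- c(standard[[par]], modified[[par]])
    g <- factor(rep(c("standard", "modified"), c(nrow(standard), nrow(modified))))
    if (stats::sd(y) == 0) {
      p <- NA_real_
      warning("robustness_anova: degenerate variance for ", par, ", p undefined")
    } else {
      p <- stats::anova(stats::lm(y ~ g))[["Pr(>F)"]][1]
    }
    data.frame(parameter = par, mean_standard = mean(standard[[par]]),
               mean_modified = mean(modified[[par]]), p_value = p,
               significant = isTRUE(p < alpha))
  }
  out <- rbind(one("K"), one("q6"))
  rownames(out) <- NULL
  out
}

#' IVRT batch equivalence test
#'
#' Ratio 90% CIs of K and Q6h between two batches, judged against the
#' 90--111% acceptance range. Uses the identical interval engine as
#' [discriminatory_power()].
#'
#' @param test,ref data.frames with columns `K`, `q6`, one row per replicate
#'   (>= 3 each; studies typically use 12).
#' @param ... Passed to [ci_ratio()].
#' @return data.frame shaped like a guideline equivalence table: per
#'   parameter n, means, SDs, ratio, CI bounds and verdict status.
#' @export
ivrt_equivalence <- function(test, ref, ...) {
  stopifnot(nrow(test) >= 3, nrow(ref) >= 3)
  one <- function(par) {
    ts <- summarize_group(test[[par]])
    rs <- summarize_group(ref[[par]])
    ci <- ci_ratio(ts, rs, ...)
    v <- range_check(ci, "ivrt_90_111")
    data.frame(parameter = par, n_test = ts$n, mean_test = ts$mean, sd_test = ts$sd,
               n_ref = rs$n, mean_ref = rs$mean, sd_ref = rs$sd,
               ratio = ci$point, lower = ci$lower, upper = ci$upper,
               status = v$status)
  }
  out <- rbind(one("K"), one("q6"))
  rownames(out) <- NULL
  out
}
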