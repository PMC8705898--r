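#' Donor replicate for skin permeation studies
#'
#' @param donor_id Skin donor identifier.
#' @param replicate_id Cell/replicate identifier.
#' @param teer_ohm Transepithelial electrical resistance (Ohm), > 0.
#' @param profile A `cumulative_profile` (q in ug/cm^2 after unit handling
#'   in [cumulative_profile()], or ng-scale values when the study works on
#'   the ng scale throughout).
#' @return An object of class `donor_replicate`.
#' @export
donor_replicate <- function(donor_id, replicate_id, teer_ohm, profile) {
  stopifnot(inherits(profile, "cumulative_profile"))
  if (!is.finite(teer_ohm) || teer_ohm <= 0)
    stop("donor_replicate: TEER must be a positive resistance")
  structure(list(donor_id = as.character(donor_id),
                 replicate_id = as.character(replicate_id),
                 teer_ohm = as.numeric(teer_ohm), profile = profile),
            class = "donor_replicate")
}

#' Skin-integrity gate on TEER
#'
#' Keeps replicates whose resistance is strictly above the cut-off
#' (2000 Ohm by default, the suitability threshold for dermatomed human
#' skin); exclusions are reported with donor and replicate ids.
#'
#' @param replicates List of [donor_replicate()] objects.
#' @param cutoff_ohm Resistance cut-off (default 2000).
#' @return List with `kept` and `excluded` (both in input order).
#' @export
teer_filter <- function(replicates, cutoff_ohm = 2000) {
  stopifnot(all(vapply(replicates, inherits, logical(1), "donor_replicate")))
  teer <- vapply(replicates, `[[`, numeric(1), "teer_ohm")
  keep <- teer > cutoff_ohm
  if (any(!keep)) {
    ids <- vapply(replicates[!keep], function(r)
      paste0(r$donor_id, "/", r$replicate_id), character(1))
    message("teer_filter: excluded ", sum(!keep), " replicate(s) at or below ",
            cutoff_ohm, " Ohm: ", paste(ids, collapse = ", "))
  }
  list(kept = replicates[keep], excluded = replicates[!keep])
}

#' Default steady-state regression window
#'
#' Among trailing contiguous windows (ending at the last sampling time) of
#' at least `min_points` points, returns the one whose linear q-vs-t fit
#' maximizes r^2; ties go to the longer window. The permeation literature
#' rarely states its window, so this reproducible rule is the default and
#' can be overridden per study.
#'
#' @param profile A `cumulative_profile`.
#' @param min_points Minimum window length (default 5).
#' @return Integer indices of the selected points.
#' @export
steady_state_window <- function(profile, min_points = 5) {
  n <- length(profile$times_h)
  if (n < min_points) return(seq_len(n))
  best <- NULL; best_r2 <- -Inf
  for (k in n:min_points) {         # longest first, so ties keep the longest
    idx <- (n - k + 1):n
    t <- profile$times_h[idx]; q <- profile$q_ug_cm2[idx]
    if (stats::sd(t) == 0) next
    fit <- stats::lm(q ~ t)
    r2 <- ols_r2(q, stats::fitted(fit))
    if (r2 > best_r2 + 1e-12) { best_r2 <- r2; best <- idx }
  }
  if (is.null(best)) seq_len(n) else best
}

#' Steady-state flux fit
#'
#' OLS of cumulative permeated amount on time over the steady-state window.
#' The slope is the steady-state flux Jss; the lag time is the x-intercept
#' `-intercept/slope` (only defined for a positive slope; negative lags are
#' reported and flagged rather than truncated). Q24h is the cumulative
#' amount at the final sampling time.
#'
#' @param profile A `cumulative_profile`.
#' @param window Optional `c(t_min, t_max)`; default
#'   [steady_state_window()].
#' @return An object of class `permeation_params`: `jss`, `lag`, `r2`,
#'   `q24`, `replicate_id`.
#' @export
flux_fit <- function(profile, window = NULL) {
  stopifnot(inherits(profile, "cumulative_profile"))
  if (is.null(window)) {
    idx <- steady_state_window(profile)
  } else {
    idx <- which(profile$times_h >= window[1] & profile$times_h <= window[2])
  }
  t <- profile$times_h[idx]; q <- profile$q_ug_cm2[idx]
  if (length(t) < 3) stop("flux_fit: need at least 3 points in the window")
  fit <- stats::lm(q ~ t)
  jss <- unname(stats::coef(fit)[2])
  b0 <- unname(stats::coef(fit)[1])
  # slope indistinguishable from zero at round-off scale counts as flat
  tol <- 1e-10 * (1 + max(abs(q))) / diff(range(t))
  flat <- jss <= tol
  lag <- if (!flat) -b0 / jss else NA_real_
  if (flat) warning("flux_fit [", profile$replicate_id,
                    "]: non-positive slope, lag time undefined")
  structure(
    list(jss = jss, lag = lag, r2 = ols_r2(q, stats::fitted(fit)),
         q24 = profile$q_ug_cm2[length(profile$q_ug_cm2)],
         replicate_id = profile$replicate_id),
    class = "permeation_params"
  )
}

#' @export
print.permeation_params <- function(x, ...) {
  cat(sprintf("Flux fit [%s]: Jss = %.3f /h/cm^2, lag = %.2f h, r2 = %.4f, Q24h = %.3f /cm^2\n",
              x$replicate_id, x$jss, x$lag, x$r2, x$q24))
  invisible(x)
}

#' Per-donor geometric means of permeation parameters
#'
#' Collapses the replicate level first: within each donor the geometric
#' mean of Jss and Q24h is taken, and all downstream statistics operate on
#' the n-donor list. Donors with any non-positive value are excluded with a
#' diagnostic (geometric means require positivity).
#'
#' @param params data.frame with columns `donor_id`, `jss`, `q24`.
#' @return data.frame with one row per donor: `donor_id`, `jss`, `q24`.
#' @export
donor_geomean <- function(params) {
  stopifnot(all(c("donor_id", "jss", "q24") %in% names(params)))
  rows <- lapply(split(params, params$donor_id), function(d) {
    if (any(d$jss <= 0) || any(d$q24 <= 0)) {
      warning("donor_geomean: donor '", d$donor_id[1],
              "' excluded (non-positive parameter value)")
      return(NULL)
    }
    data.frame(donor_id = d$donor_id[1],
               jss = exp(mean(log(d$jss))), q24 = exp(mean(log(d$q24))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' IVPT batch equivalence test
#'
#' Log-scale ratio 90% CIs ([ci_ratio_log()]) of per-donor geometric means
#' of flux and Q24h between two arms, judged against the 80--125%
#' bioequivalence range. Also reports the plain geometric-mean ratio in
#' percent.
#'
#' @param test,ref data.frames of per-donor values with columns `jss`,
#'   `q24` (>= 3 donors each; pilot studies typically use 6).
#' @param alpha Two-sided error rate (default 0.10).
#' @return data.frame per parameter: n, geometric means, ratio (%), CI
#'   bounds and verdict status.
#' @export
ivpt_equivalence <- function(test, ref, alpha = 0.10) {
  stopifnot(nrow(test) >= 3, nrow(ref) >= 3)
  one <- function(par) {
    ci <- ci_ratio_log(test[[par]], ref[[par]], alpha = alpha)
    v <- range_check(ci, "ivpt_80_125")
    data.frame(parameter = par,
               n_test = nrow(test), gm_test = exp(mean(log(test[[par]]))),
               n_ref = nrow(ref), gm_ref = exp(mean(log(ref[[par]]))),
               ratio_pct = 100 * ci$point, lower = ci$lower, upper = ci$upper,
               status = v$status)
  }
  out <- rbind(one("jss"), one("q24"))
  rownames(out) <- NULL
  out
}

#' Mass balance of a permeation experiment
#'
#' Recovery of the applied dose as receptor + skin-retained + residual
#' (non-permeated) drug, in percent; individual cells outside the nominal
#' 90--110% window are flagged, and a cohort summary (mean, min, max) is
#' returned.
#'
#' @param receptor_ug,skin_ug,residual_ug Drug amounts per cell (ug),
#'   vectors of equal length, non-negative.
#' @param applied_ug Applied dose per cell (ug), positive (recycled if
#'   scalar).
#' @return List with `cells` (per-cell data.frame incl. `recovery_pct` and
#'   `flag` in `low`/`ok`/`high`) and `summary` (mean/min/max recovery).
#' @export
mass_balance <- function(receptor_ug, skin_ug, residual_ug, applied_ug) {
  n <- length(receptor_ug)
  stopifnot(length(skin_ug) == n, length(residual_ug) == n)
  applied_ug <- rep_len(applied_ug, n)
  if (any(applied_ug <= 0)) stop("mass_balance: applied dose must be positive")
  if (any(c(receptor_ug, skin_ug, residual_ug) < 0))
    stop("mass_balance: drug amounts must be non-negative")
  rec <- 100 * (receptor_ug + skin_ug + residual_ug) / applied_ug
  flag <- ifelse(rec < 90, "low", ifelse(rec > 110, "high", "ok"))
  cells <- data.frame(receptor_ug = receptor_ug, skin_ug = skin_ug,
                      residual_ug = residual_ug, applied_ug = applied_ug,
                      recovery_pct = rec, flag = flag)
  list(cells = cells,
       summary = c(mean = mean(rec), min = min(rec), max = max(rec)))
}
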