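#' Summary-level equivalence report
#'
#' The guideline verdict for one parameter from batch summaries alone:
#' ratio 90% CI plus its position relative to a named acceptance range.
#'
#' @param test,ref [group_summary()] objects.
#' @param range_name One of `names(equivalence_ranges())`.
#' @param parameter Label carried into the report.
#' @param ... Passed to [ci_ratio()].
#' @return List of class `equivalence_report` with `ci`, `verdict` and the
#'   input summaries.
#' @export
equivalence_report <- function(test, ref, range_name, parameter = "parameter", ...) {
  ci <- ci_ratio(test, ref, ...)
  v <- range_check(ci, range_name)
  structure(list(parameter = parameter, test = test, ref = ref,
                 ci = ci, verdict = v),
            class = "equivalence_report")
}

#' @export
print.equivalence_report <- function(x, ...) {
  cat("Equivalence report:", x$parameter, "\n")
  cat(sprintf("  test: mean %.4f, SD %.4f, n %d\n", x$test$mean, x$test$sd, x$test$n))
  cat(sprintf("  ref:  mean %.4f, SD %.4f, n %d\n", x$ref$mean, x$ref$sd, x$ref$n))
  cat(sprintf("  ratio %.2f%%, 90%% CI [%.4f, %.4f], df %.2f\n",
              100 * x$ci$point, x$ci$lower, x$ci$upper, x$ci$df))
  cat(sprintf("  vs %s [%g, %g]: %s\n", x$verdict$range_name,
              x$verdict$range[1], x$verdict$range[2], x$verdict$status))
  invisible(x)
}

#' JSON verdict schema for a ratio interval
#'
#' `{range, point, lower, upper, df, status}` — the machine-readable form
#' of an equivalence verdict.
#'
#' @param ci A ratio-scale `ci_result`.
#' @param range_name Acceptance range name.
#' @return JSON string.
#' @export
verdict_json <- function(ci, range_name) {
  v <- range_check(ci, range_name)
  jsonlite::toJSON(list(range = range_name, point = ci$point,
                        lower = ci$lower, upper = ci$upper,
                        df = ci$df, status = v$status),
                   auto_unbox = TRUE, digits = NA, na = "null")
}

#' End-to-end IVRT equivalence study
#'
#' From raw sampling records per batch to the equivalence table: builds
#' corrected cumulative profiles, fits Higuchi kinetics per replicate, and
#' compares every test batch against the reference batch.
#'
#' @param records_by_batch Named list (one element per batch) of lists of
#'   [sampling_record()] objects.
#' @param ref Name of the reference batch (default: the last one).
#' @param cell Cell geometry (default [ivrt_cell()]).
#' @param ... Passed to [higuchi_fit()].
#' @return List with `params` (per-batch release tables) and `equivalence`
#'   (stacked [ivrt_equivalence()] tables, one comparison per test batch).
#' @export
ivrt_study <- function(records_by_batch, ref = NULL, cell = ivrt_cell(), ...) {
  stopifnot(is.list(records_by_batch), length(records_by_batch) >= 2,
            !is.null(names(records_by_batch)))
  if (is.null(ref)) ref <- names(records_by_batch)[length(records_by_batch)]
  params <- lapply(records_by_batch, function(recs)
    release_table(lapply(recs, cumulative_profile, cell = cell), ...))
  tests <- setdiff(names(params), ref)
  eq <- do.call(rbind, lapply(tests, function(b) {
    tab <- ivrt_equivalence(params[[b]], params[[ref]])
    cbind(comparison = paste0(b, " vs ", ref), tab)
  }))
  rownames(eq) <- NULL
  list(params = params, equivalence = eq)
}

#' End-to-end IVPT equivalence study
#'
#' TEER integrity gate, steady-state flux fits, per-donor geometric means,
#' and log-scale equivalence of every test arm against the reference arm.
#'
#' @param records_by_arm Named list (per arm) of annotated sampling
#'   records (`donor_id`/`teer_ohm` attributes).
#' @param ref Name of the reference arm (default: the first one).
#' @param cell Cell geometry (default [ivpt_cell()]).
#' @param teer_cutoff TEER cut-off (Ohm, default 2000).
#' @return List with `donor_means` (per-arm data.frames), `excluded`
#'   (TEER-failed replicate ids per arm) and `equivalence` (stacked
#'   [ivpt_equivalence()] tables).
#' @export
ivpt_study <- function(records_by_arm, ref = NULL, cell = ivpt_cell(),
                       teer_cutoff = 2000) {
  stopifnot(is.list(records_by_arm), length(records_by_arm) >= 2,
            !is.null(names(records_by_arm)))
  if (is.null(ref)) ref <- names(records_by_arm)[1]
  per_arm <- lapply(records_by_arm, function(recs) {
    reps <- as_donor_replicates(recs, cell)
    flt <- teer_filter(reps, teer_cutoff)
    fits <- lapply(flt$kept, function(dr) {
      f <- flux_fit(dr$profile)
      data.frame(donor_id = dr$donor_id, jss = f$jss, q24 = f$q24)
    })
    list(donor_means = donor_geomean(do.call(rbind, fits)),
         excluded = vapply(flt$excluded, function(r)
           paste0(r$donor_id, "/", r$replicate_id), character(1)))
  })
  tests <- setdiff(names(per_arm), ref)
  eq <- do.call(rbind, lapply(tests, function(a) {
    tab <- ivpt_equivalence(per_arm[[a]]$donor_means, per_arm[[ref]]$donor_means)
    cbind(comparison = paste0(a, " vs ", ref), tab)
  }))
  rownames(eq) <- NULL
  list(donor_means = lapply(per_arm, `[[`, "donor_means"),
       excluded = lapply(per_arm, `[[`, "excluded"),
       equivalence = eq)
}

#' End-to-end rheology comparison study
#'
#' Derives the five descriptors for each replicate flow-curve/sweep pair
#' and runs the physicochemical equivalence comparison.
#'
#' @param test,ref Lists of `list(curve = flow_curve, sweep = osc_sweep)`
#'   replicate pairs.
#' @return List with `params` (per-arm descriptor tables) and
#'   `equivalence` ([rheo_equivalence()] table).
#' @export
rheology_study <- function(test, ref) {
  tab <- function(arm) do.call(rbind, lapply(arm, function(p)
    rheo_params(p$curve, p$sweep)))
  pt <- tab(test); pr <- tab(ref)
  list(params = list(test = pt, ref = pr),
       equivalence = rheo_equivalence(pt, pr))
}

#' End-to-end microstructure comparison study
#'
#' Droplet-size equivalence with normality screening, plus XRD peak
#' detection and Type I/II pattern classification per batch.
#'
#' @param droplets Named list of diameter vectors per batch (first element
#'   is the test, second the reference for the equivalence comparison).
#' @param diffractograms Optional named list of [diffractogram()] objects.
#' @param min_prominence Peak-detection prominence threshold (counts,
#'   default 50).
#' @return List with `droplet` (per-batch stats + equivalence) and `xrd`
#'   (per-batch classification tables with detected peaks).
#' @export
microstructure_study <- function(droplets, diffractograms = NULL,
                                 min_prominence = 50) {
  stopifnot(length(droplets) >= 2)
  stats <- lapply(droplets, droplet_stats)
  eq <- droplet_equivalence(droplets[[1]], droplets[[2]])
  xrd <- NULL
  if (!is.null(diffractograms)) {
    xrd <- lapply(diffractograms, function(d) {
      pk <- detect_peaks(d, min_prominence = min_prominence)
      list(peaks = pk, classification = classify_pattern(pk$two_theta_deg))
    })
  }
  list(droplet = list(stats = stats, equivalence = eq), xrd = xrd)
}

#' Write a study report as machine-readable JSON
#'
#' @param report Any report list produced by the `_study` functions.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
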