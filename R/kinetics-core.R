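#' Franz diffusion cell configuration
#'
#' Geometry and dosing metadata of a vertical (Franz) diffusion cell. The
#' receptor volume and per-draw sample volume drive the sampling-replacement
#' mass-balance correction in [cumulative_profile()].
#'
#' @param receptor_volume_ml Receptor compartment volume (mL).
#' @param sample_volume_ml Volume withdrawn (and replaced) at each sampling
#'   time (mL); must be smaller than the receptor volume.
#' @param diffusion_area_cm2 Effective diffusion area (cm^2).
#' @param applied_dose_mg Formulation mass placed in the donor compartment
#'   (mg), optional metadata.
#' @param temperature_c Experiment temperature (degrees C), optional metadata.
#'
#' @return An object of class `cell_config`.
#' @examples
#' ivrt_cell()   # 12 mL / 0.3 mL / 1.54 cm^2, the standard IVRT setup
#' @export
cell_config <- function(receptor_volume_ml, sample_volume_ml, diffusion_area_cm2,
                        applied_dose_mg = NA_real_, temperature_c = NA_real_) {
  stopifnot(
    is.numeric(receptor_volume_ml), length(receptor_volume_ml) == 1L,
    is.numeric(sample_volume_ml), length(sample_volume_ml) == 1L,
    is.numeric(diffusion_area_cm2), length(diffusion_area_cm2) == 1L
  )
  if (receptor_volume_ml <= 0 || sample_volume_ml <= 0 || diffusion_area_cm2 <= 0)
    stop("cell_config: receptor volume, sample volume and diffusion area must all be positive")
  if (sample_volume_ml >= receptor_volume_ml)
    stop("cell_config: sample_volume_ml must be smaller than receptor_volume_ml")
  structure(
    list(
      receptor_volume_ml = as.numeric(receptor_volume_ml),
      sample_volume_ml = as.numeric(sample_volume_ml),
      diffusion_area_cm2 = as.numeric(diffusion_area_cm2),
      applied_dose_mg = as.numeric(applied_dose_mg),
      temperature_c = as.numeric(temperature_c)
    ),
    class = "cell_config"
  )
}

#' @rdname cell_config
#' @export
ivrt_cell <- function() {
  cell_config(receptor_volume_ml = 12, sample_volume_ml = 0.3,
              diffusion_area_cm2 = 1.54, applied_dose_mg = 600,
              temperature_c = 37)
}

#' @rdname cell_config
#' @export
ivpt_cell <- function() {
  # 1 cm^2 skin window; 7 mL receptor is a typical jacketed-cell volume
  cell_config(receptor_volume_ml = 7, sample_volume_ml = 0.3,
              diffusion_area_cm2 = 1, applied_dose_mg = 50,
              temperature_c = 32)
}

#' @export
print.cell_config <- function(x, ...) {
  cat("Franz cell: receptor", x$receptor_volume_ml, "mL, sample",
      x$sample_volume_ml, "mL, area", x$diffusion_area_cm2, "cm^2\n")
  invisible(x)
}

#' Raw receptor sampling record for one replicate cell
#'
#' Time-ordered receptor concentrations as drawn from the sampling port,
#' before any correction for the analyte removed by earlier draws.
#'
#' @param replicate_id Identifier of the cell/replicate.
#' @param times_h Strictly increasing, non-negative sampling times (h).
#' @param concentrations Measured receptor concentrations, same length as
#'   `times_h`, non-negative.
#' @param unit Concentration unit, `"ug/mL"` (IVRT/HPLC scale) or `"ng/mL"`
#'   (IVPT/HPLC-MS scale).
#'
#' @return An object of class `sampling_record`.
#' @export
sampling_record <- function(replicate_id, times_h, concentrations,
                            unit = c("ug/mL", "ng/mL")) {
  unit <- match.arg(unit)
  times_h <- as.numeric(times_h)
  concentrations <- as.numeric(concentrations)
  if (length(times_h) != length(concentrations))
    stop(sprintf("sampling_record '%s': times and concentrations differ in length (%d vs %d)",
                 replicate_id, length(times_h), length(concentrations)))
  if (length(times_h) == 0L)
    stop(sprintf("sampling_record '%s': empty record", replicate_id))
  if (any(times_h < 0) || any(diff(times_h) <= 0))
    stop(sprintf("sampling_record '%s': times must be non-negative and strictly increasing",
                 replicate_id))
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    stop(sprintf("sampling_record '%s': concentrations must be finite and non-negative",
                 replicate_id))
  structure(
    list(replicate_id = as.character(replicate_id), times_h = times_h,
         concentrations = concentrations, unit = unit),
    class = "sampling_record"
  )
}

#' Sampling-replacement-corrected cumulative release profile
#'
#' Converts raw receptor concentrations into the cumulative drug amount per
#' unit area. Each draw removes `sample_volume` of receptor fluid which is
#' replaced by fresh medium, so the drug present at draw n is the receptor
#' content plus everything carried away by earlier draws:
#'
#'   Q_n = (C_n * V_receptor + sum_{i<n} C_i * V_sample) / A
#'
#' Concentrations declared in ng/mL are converted to ug internally; the
#' canonical output unit is ug/cm^2. Q is not forced to be monotone: assay
#' noise may produce local decreases, which are preserved.
#'
#' @param record A [sampling_record()].
#' @param cell A [cell_config()].
#' @param correct_sampling Apply the replacement correction (default `TRUE`);
#'   with `FALSE` only the receptor term `C_n * V / A` is used.
#'
#' @return An object of class `cumulative_profile` with fields
#'   `replicate_id`, `times_h` and `q_ug_cm2`.
#' @examples
#' rec <- sampling_record("r1", c(1, 2, 3), c(1, 2, 3))
#' cel <- cell_config(12, 0.3, 1)
#' cumulative_profile(rec, cel)$q_ug_cm2   # 12.0 24.3 36.9
#' @export
cumulative_profile <- function(record, cell, correct_sampling = TRUE) {
  stopifnot(inherits(record, "sampling_record"), inherits(cell, "cell_config"))
  conc <- record$concentrations
  if (record$unit == "ng/mL") conc <- conc / 1000  # -> ug/mL
  vs <- if (isTRUE(correct_sampling)) cell$sample_volume_ml else 0
  prior <- c(0, cumsum(conc * vs))[seq_along(conc)]
  q <- (conc * cell$receptor_volume_ml + prior) / cell$diffusion_area_cm2
  structure(
    list(replicate_id = record$replicate_id, times_h = record$times_h,
         q_ug_cm2 = q),
    class = "cumulative_profile"
  )
}

#' @export
print.cumulative_profile <- function(x, ...) {
  cat("Cumulative release profile [", x$replicate_id, "], ",
      length(x$times_h), " time points, Q(final) = ",
      signif(x$q_ug_cm2[length(x$q_ug_cm2)], 4), " ug/cm^2\n", sep = "")
  invisible(x)
}

#' Interpolate a cumulative profile at a given time
#'
#' Exact value at a sampled time, linear interpolation between sampled
#' times. Extrapolation outside the sampled range is refused.
#'
#' @param profile A `cumulative_profile`.
#' @param t Query time (h), scalar.
#' @return Cumulative amount per area (ug/cm^2) at `t`.
#' @export
interpolate_q <- function(profile, t) {
  stopifnot(inherits(profile, "cumulative_profile"), length(t) == 1L, is.finite(t))
  tt <- profile$times_h
  if (t < tt[1] || t > tt[length(tt)])
    stop(sprintf("interpolate_q: t = %g h outside sampled range [%g, %g]",
                 t, tt[1], tt[length(tt)]))
  stats::approx(tt, profile$q_ug_cm2, xout = t, method = "linear",
                ties = "ordered")$y
}

#' Read Franz-cell sampling records from a long-format CSV
#'
#' Expects columns `replicate_id`, `time_h`, `concentration` and `unit`
#' (one unit per replicate). Optional extra columns `donor_id` and
#' `teer_ohm` are carried through for IVPT use.
#'
#' @param path CSV file path.
#' @return A named list of [sampling_record()] objects; IVPT metadata, when
#'   present, is attached as attributes `donor_id` and `teer_ohm` on each
#'   record.
#' @export
read_sampling_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("replicate_id", "time_h", "concentration", "unit")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_sampling_csv: missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("read_sampling_csv: empty input file: ", path)
  recs <- lapply(split(df, df$replicate_id), function(d) {
    d <- d[order(d$time_h), , drop = FALSE]
    u <- unique(d$unit)
    if (length(u) != 1L)
      stop("read_sampling_csv: replicate '", d$replicate_id[1], "' mixes units")
    r <- sampling_record(d$replicate_id[1], d$time_h, d$concentration, unit = u)
    if ("donor_id" %in% names(d)) attr(r, "donor_id") <- as.character(d$donor_id[1])
    if ("teer_ohm" %in% names(d)) attr(r, "teer_ohm") <- as.numeric(d$teer_ohm[1])
    r
  })
  recs[order(names(recs))]
}

#' Write cumulative profiles as tidy CSV
#'
#' @param profiles A list of `cumulative_profile` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  stopifnot(all(vapply(profiles, inherits, logical(1), "cumulative_profile")))
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(replicate_id = p$replicate_id, time_h = p$times_h,
               q_ug_cm2 = p$q_ug_cm2)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
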