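#' Default IVRT and IVPT sampling schedules
#'
#' The standard schedules: IVRT up to 6 h (0.5, 1, 2, 3, 4, 5, 6 h) and
#' IVPT up to 24 h (0, 1.5, 2.5, 3.5, 5.5, 7.5, 9.5, 11.5, 14.5, 17.5,
#' 20.5, 24 h).
#'
#' @return Numeric vector of sampling times (h).
#' @export
ivrt_times <- function() c(0.5, 1, 2, 3, 4, 5, 6)

#' @rdname ivrt_times
#' @export
ivpt_times <- function() c(0, 1.5, 2.5, 3.5, 5.5, 7.5, 9.5, 11.5, 14.5, 17.5, 20.5, 24)

# lognormal parameters matching a target arithmetic mean and SD
lognormal_match <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

# invert a cumulative amount-per-area series to the receptor concentrations
# that reproduce it through the sampling-replacement correction
invert_correction <- function(q, cell) {
  conc <- numeric(length(q))
  carried <- 0
  for (i in seq_along(q)) {
    conc[i] <- max(0, (q[i] * cell$diffusion_area_cm2 - carried) /
                        cell$receptor_volume_ml)
    carried <- carried + conc[i] * cell$sample_volume_ml
  }
  conc
}

#' Simulate IVRT sampling records
#'
#' Square-root-of-time (Higuchi) release: per replicate the release
#' constant is drawn lognormally around `true_K` with coefficient of
#' variation `replicate_cv`, cumulative amounts q(t) = K sqrt(t) + eps with
#' additive Gaussian noise are formed, and the series is inverted through
#' the Franz sampling-replacement correction so that concentration records
#' (not q) are emitted — the pipeline's correction code path is always
#' exercised on the way back.
#'
#' @param n_replicates Number of cells.
#' @param true_K Release constant (ug h^-1/2 cm^-2); defaults near the
#'   ~28 of a 0.025% capsaicin emulsion.
#' @param replicate_cv Between-cell CV of K (default 0.08, matching
#'   single-digit-percent release precision).
#' @param noise_sd Additive SD on q (ug/cm^2, default 1).
#' @param times_h Sampling schedule (default [ivrt_times()]).
#' @param cell Cell geometry (default [ivrt_cell()]).
#' @param strength Formulation strength (% w/w) scaling K proportionally
#'   (default 0.025, i.e. scale 1 relative to `true_K`).
#' @param seed Mandatory RNG seed.
#' @param prefix Replicate id prefix.
#' @return List of [sampling_record()] objects.
#' @export
gen_release <- function(n_replicates, true_K = 28, replicate_cv = 0.08,
                        noise_sd = 1, times_h = ivrt_times(),
                        cell = ivrt_cell(), strength = 0.025, seed,
                        prefix = "rep") {
  if (missing(seed)) stop("gen_release: a seed is required")
  set.seed(seed)
  k_scale <- strength / 0.025
  sdlog <- cv_to_sdlog(replicate_cv)
  lapply(seq_len(n_replicates), function(i) {
    k_i <- true_K * k_scale * exp(stats::rnorm(1, -sdlog^2 / 2, sdlog))
    q <- k_i * sqrt(times_h) + stats::rnorm(length(times_h), 0, noise_sd)
    q <- pmax(q, 0)
    sampling_record(sprintf("%s%02d", prefix, i), times_h,
                    invert_correction(q, cell), unit = "ug/mL")
  })
}

#' Simulate IVPT donor replicates
#'
#' Zero-order permeation after a lag: q(t) = Jss_eff max(t - lag, 0) with a
#' multiplicative lognormal hierarchy — a donor effect with CV `donor_cv`
#' shared by a donor's replicates and a replicate effect with CV
#' `replicate_cv` — plus multiplicative measurement noise. Concentration
#' records on the ng/mL scale are emitted together with simulated TEER
#' values; a configurable fraction of cells fails the 2000-Ohm integrity
#' gate.
#'
#' @param n_donors Number of skin donors.
#' @param reps_per_donor Replicates per donor (default 2).
#' @param true_jss Steady-state flux (ng h^-1 cm^-2, default 15).
#' @param true_lag Lag time (h, default 2).
#' @param donor_cv Donor-to-donor CV (default 0.5 — skin permeation SDs of
#'   50--60% of the mean are typical).
#' @param replicate_cv Within-donor CV (default 0.15).
#' @param noise_cv Multiplicative per-point noise CV (default 0.05).
#' @param times_h Sampling schedule (default [ivpt_times()]).
#' @param cell Cell geometry (default [ivpt_cell()]).
#' @param teer_fail_fraction Expected fraction of cells below the TEER
#'   cut-off (default 0).
#' @param seed Mandatory RNG seed.
#' @param prefix Donor id prefix.
#' @return List of [sampling_record()] objects carrying `donor_id` and
#'   `teer_ohm` attributes (the same shape [read_sampling_csv()] returns
#'   for IVPT files); convert with [as_donor_replicates()].
#' @export
gen_permeation <- function(n_donors, reps_per_donor = 2, true_jss = 15,
                           true_lag = 2, donor_cv = 0.5, replicate_cv = 0.15,
                           noise_cv = 0.05, times_h = ivpt_times(),
                           cell = ivpt_cell(), teer_fail_fraction = 0, seed,
                           prefix = "donor") {
  if (missing(seed)) stop("gen_permeation: a seed is required")
  set.seed(seed)
  sd_d <- cv_to_sdlog(donor_cv)
  sd_r <- cv_to_sdlog(replicate_cv)
  out <- list()
  for (d in seq_len(n_donors)) {
    donor_eff <- exp(stats::rnorm(1, -sd_d^2 / 2, sd_d))
    for (r in seq_len(reps_per_donor)) {
      jss_eff <- true_jss * donor_eff * exp(stats::rnorm(1, -sd_r^2 / 2, sd_r))
      q <- jss_eff * pmax(times_h - true_lag, 0)
      q <- q * exp(stats::rnorm(length(q), 0, cv_to_sdlog(noise_cv)))
      teer <- if (stats::runif(1) < teer_fail_fraction)
        stats::runif(1, 800, 2000) else stats::runif(1, 2200, 4500)
      rec <- sampling_record(sprintf("%s%02d_r%d", prefix, d, r), times_h,
                             invert_correction(q, cell), unit = "ng/mL")
      attr(rec, "donor_id") <- sprintf("%s%02d", prefix, d)
      attr(rec, "teer_ohm") <- teer
      out[[length(out) + 1L]] <- rec
    }
  }
  out
}

#' Build donor replicates from annotated sampling records
#'
#' @param records Sampling records carrying `donor_id` and `teer_ohm`
#'   attributes (from [gen_permeation()] or [read_sampling_csv()]).
#' @param cell Cell geometry used for the cumulative correction.
#' @return List of [donor_replicate()] objects.
#' @export
as_donor_replicates <- function(records, cell) {
  lapply(records, function(r) {
    donor_replicate(attr(r, "donor_id"), r$replicate_id, attr(r, "teer_ohm"),
                    cumulative_profile(r, cell))
  })
}

#' Simulate a thixotropic flow loop
#'
#' Herschel--Bulkley up ramp sigma = sigma0 + k gamma-dot^n over 0--300
#' 1/s, a hold segment at 300 1/s, and a down ramp scaled to
#' `(1 - thixo_fraction)` of the up-ramp stress — so the relative
#' thixotropic loop area converges to `100 * thixo_fraction` as the grid
#' refines (exactly, for this proportional loop shape).
#'
#' @param yield_stress_pa Herschel--Bulkley yield stress sigma0 (Pa,
#'   default 20).
#' @param consistency_k Consistency index k (Pa s^n, default 3).
#' @param flow_index Flow behaviour index n (default 0.6).
#' @param thixo_fraction Fractional loop area (default 0.526, a typical
#'   value for an aged o/w emulsion).
#' @param n_points Points per ramp (default 200).
#' @param noise_sd Additive stress noise (Pa, default 0).
#' @param seed Mandatory RNG seed (used only when `noise_sd > 0`, but
#'   always required for reproducibility discipline).
#' @return A [flow_curve()].
#' @export
gen_flow_curve <- function(yield_stress_pa = 20, consistency_k = 3,
                           flow_index = 0.6, thixo_fraction = 0.526,
                           n_points = 200, noise_sd = 0, seed) {
  if (missing(seed)) stop("gen_flow_curve: a seed is required")
  set.seed(seed)
  rates <- seq(0, 300, length.out = n_points)
  hb <- function(g) yield_stress_pa * (g > 0) + consistency_k * g^flow_index
  up_s <- hb(rates) + stats::rnorm(n_points, 0, noise_sd)
  down_s <- (1 - thixo_fraction) * hb(rates) + stats::rnorm(n_points, 0, noise_sd)
  hold_s <- rep(hb(300), 20) + stats::rnorm(20, 0, noise_sd)
  flow_curve(
    up = data.frame(shear_rate = rates, shear_stress = up_s),
    hold = data.frame(shear_rate = rep(300, 20), shear_stress = hold_s),
    down = data.frame(shear_rate = rev(rates), shear_stress = rev(down_s))
  )
}

#' Simulate an oscillatory stress sweep
#'
#' Constant G' plateau up to a critical stress, then a power-law decay
#' `G'(sigma) = plateau (sigma/sigma_c)^(-decay_exponent)`; G'' follows a
#' constant phase angle. A zero decay exponent produces a sweep with no
#' yield (the error path of [yield_stress()]).
#'
#' @param g_prime_plateau Plateau storage modulus (Pa, default 1300).
#' @param delta_deg Phase angle (degrees, default 25).
#' @param critical_stress Onset of yielding (Pa, default 74.2).
#' @param decay_exponent Post-yield power-law exponent (default 8).
#' @param n_per_decade Stress points per decade over 0.1--1000 Pa
#'   (default 25).
#' @param noise_cv Multiplicative modulus noise CV (default 0).
#' @param seed Mandatory RNG seed.
#' @return An [osc_sweep()].
#' @export
gen_osc_sweep <- function(g_prime_plateau = 1300, delta_deg = 25,
                          critical_stress = 74.2, decay_exponent = 8,
                          n_per_decade = 25, noise_cv = 0, seed) {
  if (missing(seed)) stop("gen_osc_sweep: a seed is required")
  set.seed(seed)
  stress <- 10^seq(log10(0.1), log10(1000), by = 1 / n_per_decade)
  gp <- g_prime_plateau *
    ifelse(stress <= critical_stress | decay_exponent == 0, 1,
           (stress / critical_stress)^(-decay_exponent))
  if (noise_cv > 0)
    gp <- gp * exp(stats::rnorm(length(gp), 0, cv_to_sdlog(noise_cv)))
  gpp <- gp * tan(delta_deg * pi / 180)
  osc_sweep(stress, gp, gpp)
}

#' Simulate a droplet-diameter sample
#'
#' Lognormal diameters with parameters solved so the distribution's
#' arithmetic mean and SD match the targets (moment matching) — the
#' right-skewed, non-normal shape real emulsion droplet measurements show.
#'
#' @param mean_um,sd_um Target arithmetic mean and SD (um).
#' @param n Sample size (default 500).
#' @param seed Mandatory RNG seed.
#' @return Numeric vector of diameters (um).
#' @export
gen_droplets <- function(mean_um, sd_um, n = 500, seed) {
  if (missing(seed)) stop("gen_droplets: a seed is required")
  set.seed(seed)
  p <- lognormal_match(mean_um, sd_um)
  stats::rlnorm(n, p$meanlog, p$sdlog)
}

#' Simulate a powder diffractogram
#'
#' Gaussian reflections at the requested positions superimposed on a broad
#' amorphous hump, with additive Gaussian counting noise, on a uniform
#' 2-theta grid over the 3--50 degree acquisition window.
#'
#' @param peak_positions_deg Reflection positions (degrees 2-theta).
#' @param peak_height Peak amplitude(s), recycled (default 1000 counts).
#' @param peak_fwhm_deg Reflection full width at half maximum (default 0.3).
#' @param hump_center_deg,hump_sd_deg,hump_height Amorphous hump Gaussian
#'   parameters (defaults 20, 8, 300).
#' @param noise_sd Additive noise SD (counts, default 10).
#' @param step_deg Grid step (default 0.05 degrees).
#' @param seed Mandatory RNG seed.
#' @return A [diffractogram()].
#' @export
gen_diffractogram <- function(peak_positions_deg, peak_height = 1000,
                              peak_fwhm_deg = 0.3, hump_center_deg = 20,
                              hump_sd_deg = 8, hump_height = 300,
                              noise_sd = 10, step_deg = 0.05, seed) {
  if (missing(seed)) stop("gen_diffractogram: a seed is required")
  set.seed(seed)
  tt <- seq(3, 50, by = step_deg)
  peak_height <- rep_len(peak_height, length(peak_positions_deg))
  sigma <- peak_fwhm_deg / (2 * sqrt(2 * log(2)))
  y <- hump_height * exp(-0.5 * ((tt - hump_center_deg) / hump_sd_deg)^2)
  for (i in seq_along(peak_positions_deg))
    y <- y + peak_height[i] * exp(-0.5 * ((tt - peak_positions_deg[i]) / sigma)^2)
  y <- pmax(0, y + stats::rnorm(length(tt), 0, noise_sd))
  diffractogram(tt, y)
}

#' Default study scenario
#'
#' The design of a three-batch pilot equivalence study of a 0.025% w/w
#' capsaicin emulsion: three IVRT batches of 12 replicates each with
#' release constants near 28 ug h^-1/2 cm^-2, and an IVPT arm set of two
#' reference batches plus a double-strength negative control, six donors
#' by two replicates each, with heavy (CV 0.5) donor-to-donor lognormal
#' variability.
#'
#' @param seed Base seed; each arm derives its own sub-seed from it.
#' @return A list of class `study_scenario` with `ivrt` and `ivpt` arm
#'   tables and the sampling schedules.
#' @export
study_scenario <- function(seed) {
  if (missing(seed)) stop("study_scenario: a seed is required")
  structure(list(
    seed = seed,
    ivrt_times = ivrt_times(),
    ivpt_times = ivpt_times(),
    ivrt = data.frame(
      label = c("batch1", "batch2", "batch3"),
      strength = 0.025, n_replicates = 12,
      true_K = c(28.7, 28.1, 28.0), replicate_cv = 0.08, noise_sd = 1,
      seed = seed + 1:3
    ),
    ivpt = data.frame(
      label = c("batch1", "batch3", "negative_control"),
      strength = c(0.025, 0.025, 0.05), n_donors = 6, reps_per_donor = 2,
      true_jss = c(15, 13.6, 22.5), true_lag = 2,
      donor_cv = 0.5, replicate_cv = 0.15, noise_cv = 0.05,
      seed = seed + 11:13
    )
  ), class = "study_scenario")
}

#' Simulate every arm of a study scenario
#'
#' @param scenario A [study_scenario()].
#' @return List with `ivrt` (named list of record lists per batch) and
#'   `ivpt` (named list of annotated record lists per arm).
#' @export
simulate_study <- function(scenario) {
  stopifnot(inherits(scenario, "study_scenario"))
  ivrt <- lapply(seq_len(nrow(scenario$ivrt)), function(i) {
    a <- scenario$ivrt[i, ]
    gen_release(a$n_replicates, true_K = a$true_K, replicate_cv = a$replicate_cv,
                noise_sd = a$noise_sd, times_h = scenario$ivrt_times,
                strength = a$strength, seed = a$seed,
                prefix = paste0(a$label, "_"))
  })
  names(ivrt) <- scenario$ivrt$label
  ivpt <- lapply(seq_len(nrow(scenario$ivpt)), function(i) {
    a <- scenario$ivpt[i, ]
    gen_permeation(a$n_donors, a$reps_per_donor, true_jss = a$true_jss,
                   true_lag = a$true_lag, donor_cv = a$donor_cv,
                   replicate_cv = a$replicate_cv, noise_cv = a$noise_cv,
                   times_h = scenario$ivpt_times, seed = a$seed,
                   prefix = paste0(a$label, "_d"))
  })
  names(ivpt) <- scenario$ivpt$label
  list(ivrt = ivrt, ivpt = ivpt)
}

#' Write simulated sampling records to the long CSV dialect
#'
#' @param records List of sampling records (IVPT metadata attributes are
#'   written as columns when present).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sampling_csv <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r) {
    d <- data.frame(replicate_id = r$replicate_id, time_h = r$times_h,
                    concentration = r$concentrations, unit = r$unit)
    if (!is.null(attr(r, "donor_id"))) d$donor_id <- attr(r, "donor_id")
    if (!is.null(attr(r, "teer_ohm"))) d$teer_ohm <- attr(r, "teer_ohm")
    d
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
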