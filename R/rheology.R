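#' Shear-rate loop flow curve
#'
#' Rheometer flow-loop export: an up ramp (0 to 300 1/s), an optional hold
#' at the top rate, and a down ramp back to rest. Segments are data.frames
#' with columns `shear_rate` (1/s) and `shear_stress` (Pa).
#'
#' @param up,down Ramp segments; up rates must be non-decreasing, down
#'   rates non-increasing, all within \[0, 300\].
#' @param hold Optional hold segment at the top shear rate.
#' @param temperature_c Measurement temperature (metadata).
#' @return An object of class `flow_curve`.
#' @export
flow_curve <- function(up, down, hold = NULL, temperature_c = 25) {
  chk <- function(seg, nm) {
    stopifnot(all(c("shear_rate", "shear_stress") %in% names(seg)))
    if (any(seg$shear_rate < 0) || any(seg$shear_rate > 300))
      stop("flow_curve: ", nm, " segment shear rates outside [0, 300] 1/s")
    seg
  }
  up <- chk(up, "up"); down <- chk(down, "down")
  if (is.unsorted(up$shear_rate)) stop("flow_curve: up-ramp rates must be non-decreasing")
  if (is.unsorted(rev(down$shear_rate))) stop("flow_curve: down-ramp rates must be non-increasing")
  if (!is.null(hold)) hold <- chk(hold, "hold")
  structure(list(up = up, hold = hold, down = down,
                 temperature_c = temperature_c),
            class = "flow_curve")
}

#' Oscillatory stress sweep
#'
#' @param stress_pa Increasing oscillation stress amplitudes (Pa), within
#'   \[0.1, 1000\].
#' @param g_prime,g_double_prime Storage and loss moduli (Pa), positive.
#' @param frequency_hz Oscillation frequency (default 1 Hz).
#' @return An object of class `osc_sweep`.
#' @export
osc_sweep <- function(stress_pa, g_prime, g_double_prime, frequency_hz = 1) {
  n <- length(stress_pa)
  stopifnot(length(g_prime) == n, length(g_double_prime) == n, n >= 2)
  if (any(diff(stress_pa) <= 0)) stop("osc_sweep: stress amplitudes must be increasing")
  if (any(stress_pa < 0.1) || any(stress_pa > 1000))
    stop("osc_sweep: stress amplitudes outside [0.1, 1000] Pa")
  if (any(g_prime <= 0) || any(g_double_prime <= 0))
    stop("osc_sweep: moduli must be positive")
  structure(list(stress_pa = stress_pa, g_prime = g_prime,
                 g_double_prime = g_double_prime, frequency_hz = frequency_hz),
            class = "osc_sweep")
}

#' Apparent viscosity at a target shear rate
#'
#' Stress over shear rate at the requested rate: the mean of the hold
#' segment when one exists at that rate, otherwise linear interpolation of
#' stress on the up ramp.
#'
#' @param curve A `flow_curve`.
#' @param rate Shear rate (1/s, default 300 — the guideline comparison
#'   point).
#' @return Viscosity (Pa s).
#' @export
viscosity_at <- function(curve, rate = 300) {
  stopifnot(inherits(curve, "flow_curve"))
  if (!is.null(curve$hold) &&
      isTRUE(all(abs(curve$hold$shear_rate - rate) < 1e-9))) {
    return(mean(curve$hold$shear_stress) / rate)
  }
  up <- curve$up
  rng <- range(up$shear_rate)
  if (rate < rng[1] || rate > rng[2])
    stop(sprintf("viscosity_at: rate %g 1/s outside sampled up-ramp range [%g, %g]",
                 rate, rng[1], rng[2]))
  s <- stats::approx(up$shear_rate, up$shear_stress, xout = rate,
                     ties = "mean")$y
  s / rate
}

#' Relative thixotropic loop area
#'
#' RTLA = 100 * S_thix / S_asc, where S_asc is the trapezoidal area under
#' the up-ramp rheogram (stress vs shear rate) and S_thix = S_asc - S_desc
#' is the hysteresis-loop area between the ramps. Integration spans the
#' sampled points only; 0 for a fully reversible (reversal-symmetric) loop.
#'
#' @param curve A `flow_curve` with >= 3 points per ramp.
#' @return RTLA in percent.
#' @export
rtla <- function(curve) {
  stopifnot(inherits(curve, "flow_curve"))
  if (nrow(curve$up) < 3 || nrow(curve$down) < 3)
    stop("rtla: need at least 3 points per ramp")
  s_asc <- pracma::trapz(curve$up$shear_rate, curve$up$shear_stress)
  dn <- curve$down[order(curve$down$shear_rate), , drop = FALSE]
  s_desc <- pracma::trapz(dn$shear_rate, dn$shear_stress)
  if (s_asc <= 0) stop("rtla: non-positive up-ramp area")
  100 * (s_asc - s_desc) / s_asc
}

# First run of >= min_run consecutive points whose G' spread is below
# `spread` of their run mean; greedy extension from the earliest start.
lvr_plateau_idx <- function(sweep, min_run = 4, spread = 0.05) {
  gp <- sweep$g_prime
  n <- length(gp)
  for (start in seq_len(n - min_run + 1)) {
    end <- start + min_run - 1
    ok <- function(i, j) diff(range(gp[i:j])) < spread * mean(gp[i:j])
    if (!ok(start, end)) next
    while (end < n && ok(start, end + 1)) end <- end + 1
    return(start:end)
  }
  NULL
}

#' Oscillatory yield stress
#'
#' Locates the linear-viscoelastic plateau of G' (first run of >= 4 points
#' with < 5% spread) and returns the stress amplitude at which G' first
#' drops more than `deviation` below the plateau mean, log-interpolated
#' between the bracketing points. A crossover definition (first G' = G'')
#' is available as an alternative.
#'
#' @param sweep An `osc_sweep`.
#' @param deviation Fractional drop below the plateau defining yield
#'   (default 0.10).
#' @param method `"deviation"` (default) or `"crossover"`.
#' @return Yield stress (Pa).
#' @export
yield_stress <- function(sweep, deviation = 0.10, method = c("deviation", "crossover")) {
  stopifnot(inherits(sweep, "osc_sweep"))
  method <- match.arg(method)
  if (method == "crossover") {
    d <- sweep$g_prime - sweep$g_double_prime
    i <- which(d[-1] <= 0 & d[-length(d)] > 0)[1]
    if (is.na(i)) stop("yield_stress: no G'/G'' crossover detected")
    f <- d[i] / (d[i] - d[i + 1])
    return(exp((1 - f) * log(sweep$stress_pa[i]) + f * log(sweep$stress_pa[i + 1])))
  }
  idx <- lvr_plateau_idx(sweep)
  if (is.null(idx)) stop("yield_stress: no linear-viscoelastic plateau detected")
  plateau <- mean(sweep$g_prime[idx])
  thr <- (1 - deviation) * plateau
  below <- which(sweep$g_prime < thr)
  below <- below[below > idx[1]]
  if (!length(below)) stop("yield_stress: no yield detected (G' never drops below the plateau)")
  i <- below[1]
  # log-linear interpolation of the G' = thr crossing
  g0 <- sweep$g_prime[i - 1]; g1 <- sweep$g_prime[i]
  f <- (g0 - thr) / (g0 - g1)
  exp((1 - f) * log(sweep$stress_pa[i - 1]) + f * log(sweep$stress_pa[i]))
}

#' Linear-viscoelastic moduli
#'
#' Complex modulus G* = sqrt(G'^2 + G''^2) and phase angle
#' delta = atan(G''/G') (degrees), averaged over the LVR plateau points.
#'
#' @param sweep An `osc_sweep`.
#' @return List with `g_star` (Pa) and `delta_deg`.
#' @export
lvr_moduli <- function(sweep) {
  stopifnot(inherits(sweep, "osc_sweep"))
  idx <- lvr_plateau_idx(sweep)
  if (is.null(idx)) stop("lvr_moduli: no linear-viscoelastic plateau detected")
  gp <- sweep$g_prime[idx]; gpp <- sweep$g_double_prime[idx]
  list(g_star = mean(sqrt(gp^2 + gpp^2)),
       delta_deg = mean(atan2(gpp, gp)) * 180 / pi)
}

#' All five rheological comparison descriptors
#'
#' Viscosity at 300 1/s, RTLA, yield stress, G* and delta for one
#' flow-curve / stress-sweep pair.
#'
#' @param curve A `flow_curve`.
#' @param sweep An `osc_sweep`.
#' @param ... Passed to [yield_stress()].
#' @return An object of class `rheo_params` (also a one-row data.frame).
#' @export
rheo_params <- function(curve, sweep, ...) {
  m <- lvr_moduli(sweep)
  out <- data.frame(eta300 = viscosity_at(curve, 300), rtla = rtla(curve),
                    yield_stress = yield_stress(sweep, ...),
                    g_star = m$g_star, delta = m$delta_deg)
  class(out) <- c("rheo_params", "data.frame")
  out
}

#' Rheological batch equivalence
#'
#' Ratio 90% CI per descriptor between two batches, judged against the
#' physicochemical 90--110% range.
#'
#' @param test,ref data.frames of per-replicate descriptors (columns
#'   `eta300`, `rtla`, `yield_stress`, `g_star`, `delta`; >= 2 rows each).
#' @param ... Passed to [ci_ratio()].
#' @return data.frame per descriptor: means, SDs, ratio, CI and status.
#' @export
rheo_equivalence <- function(test, ref, ...) {
  pars <- c("eta300", "rtla", "yield_stress", "g_star", "delta")
  stopifnot(all(pars %in% names(test)), all(pars %in% names(ref)),
            nrow(test) >= 2, nrow(ref) >= 2)
  out <- do.call(rbind, lapply(pars, function(par) {
    ts <- summarize_group(test[[par]]); rs <- summarize_group(ref[[par]])
    ci <- ci_ratio(ts, rs, ...)
    v <- range_check(ci, "physchem_90_110")
    data.frame(parameter = par, mean_test = ts$mean, sd_test = ts$sd,
               mean_ref = rs$mean, sd_ref = rs$sd, ratio = ci$point,
               lower = ci$lower, upper = ci$upper, status = v$status)
  }))
  rownames(out) <- NULL
  out
}

#' Read a rheometer flow-curve CSV
#'
#' Columns: `segment` (`up`/`hold`/`down`), `shear_rate_1_per_s`,
#' `shear_stress_pa`.
#'
#' @param path CSV path.
#' @param temperature_c Metadata (default 25).
#' @return A `flow_curve`.
#' @export
read_flow_csv <- function(path, temperature_c = 25) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("segment", "shear_rate_1_per_s", "shear_stress_pa")
  if (!all(need %in% names(df)))
    stop("read_flow_csv: need columns ", paste(need, collapse = ", "))
  seg <- function(s) {
    d <- df[df$segment == s, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    data.frame(shear_rate = d$shear_rate_1_per_s, shear_stress = d$shear_stress_pa)
  }
  flow_curve(up = seg("up"), down = seg("down"), hold = seg("hold"),
             temperature_c = temperature_c)
}

#' Read an oscillatory stress-sweep CSV
#'
#' Columns: `stress_pa`, `g_prime_pa`, `g_double_prime_pa`.
#'
#' @param path CSV path.
#' @param frequency_hz Metadata (default 1).
#' @return An `osc_sweep`.
#' @export
read_osc_csv <- function(path, frequency_hz = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stress_pa", "g_prime_pa", "g_double_prime_pa")
  if (!all(need %in% names(df)))
    stop("read_osc_csv: need columns ", paste(need, collapse = ", "))
  osc_sweep(df$stress_pa, df$g_prime_pa, df$g_double_prime_pa, frequency_hz)
}
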