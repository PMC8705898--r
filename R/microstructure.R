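#' Droplet-size descriptive statistics
#'
#' Arithmetic mean, sample SD (n - 1) and a histogram of measured oil
#' droplet diameters.
#'
#' @param diameters_um Positive droplet diameters (um), n >= 2.
#' @param breaks Passed to [graphics::hist()] binning (default
#'   `"Sturges"`).
#' @return List with `mean`, `sd`, `n` and `histogram` (a `histogram`
#'   object, not plotted).
#' @export
droplet_stats <- function(diameters_um, breaks = "Sturges") {
  if (length(diameters_um) < 2) stop("droplet_stats: need at least 2 diameters")
  if (any(diameters_um <= 0)) stop("droplet_stats: diameters must be positive")
  list(mean = mean(diameters_um), sd = stats::sd(diameters_um),
       n = length(diameters_um),
       histogram = graphics::hist(diameters_um, breaks = breaks, plot = FALSE))
}

#' Anderson--Darling normality test
#'
#' Case-3 composite test (mean and SD estimated) with the small-sample
#' corrected statistic A*^2 = A^2 (1 + 0.75/n + 2.25/n^2), via
#' [nortest::ad.test()]. Used to screen droplet-size distributions before
#' applying normal-theory equivalence intervals.
#'
#' @param x Numeric sample, n >= 8.
#' @return List with `A2` (uncorrected statistic is not exposed by the
#'   backend; this is the corrected A*^2 used for the p-value) and
#'   `p_value`.
#' @export
ad_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 8) stop("ad_normality: need at least 8 observations")
  if (stats::sd(x) == 0) stop("ad_normality: zero variance")
  t <- nortest::ad.test(x)
  list(A2 = unname(t$statistic), p_value = t$p.value)
}

#' Droplet-size batch equivalence
#'
#' Ratio 90% CI of mean droplet diameters, judged against the
#' physicochemical 90--110% range. Normal-theory intervals assume
#' normality, which droplet diameters (typically right-skewed) often
#' violate; when the Anderson--Darling test rejects at 5% on either batch
#' the verdict carries a `normality_warning`.
#'
#' @param test,ref Positive diameter vectors (um), n >= 2 each.
#' @param ... Passed to [ci_ratio()].
#' @return List with `ci`, `verdict`, `normality_warning` and the two
#'   [ad_normality()] results (`NULL` when n < 8).
#' @export
droplet_equivalence <- function(test, ref, ...) {
  ci <- ci_ratio(summarize_group(test), summarize_group(ref), ...)
  v <- range_check(ci, "physchem_90_110")
  ad_t <- if (length(test) >= 8) ad_normality(test) else NULL
  ad_r <- if (length(ref) >= 8) ad_normality(ref) else NULL
  warn <- isTRUE(ad_t$p_value < 0.05) || isTRUE(ad_r$p_value < 0.05)
  list(ci = ci, verdict = v, normality_warning = warn,
       ad_test = ad_t, ad_ref = ad_r)
}

#' Powder diffractogram container
#'
#' @param two_theta_deg Increasing 2-theta grid (degrees), within the
#'   3--50 degree acquisition window.
#' @param intensity Non-negative counts, same length.
#' @param wavelength_a X-ray wavelength (Angstrom); default Cu K-alpha-1,
#'   1.5406.
#' @return An object of class `diffractogram`.
#' @export
diffractogram <- function(two_theta_deg, intensity, wavelength_a = 1.5406) {
  stopifnot(length(two_theta_deg) == length(intensity))
  if (any(diff(two_theta_deg) <= 0)) stop("diffractogram: 2-theta grid must be increasing")
  if (any(intensity < 0)) stop("diffractogram: intensities must be non-negative")
  structure(list(two_theta_deg = two_theta_deg, intensity = intensity,
                 wavelength_a = wavelength_a),
            class = "diffractogram")
}

#' Detect diffraction peaks over an amorphous hump
#'
#' Moving-average smoothing, a rolling-median baseline (2-degree window by
#' default — robust to the broad amorphous hump of semisolid samples),
#' then local maxima of the baseline-subtracted signal whose prominence
#' exceeds `min_prominence`.
#'
#' @param d A [diffractogram()] on a uniform grid (within 1%).
#' @param min_prominence Minimum height above the local baseline (counts).
#' @param smooth_window Moving-average width in points (odd; default 5).
#' @param baseline_deg Rolling-median window in degrees (default 2).
#' @return data.frame with `two_theta_deg`, `height` (raw counts at the
#'   peak) and `prominence`.
#' @export
detect_peaks <- function(d, min_prominence, smooth_window = 5, baseline_deg = 2) {
  stopifnot(inherits(d, "diffractogram"))
  if (!length(d$intensity)) stop("detect_peaks: empty trace")
  h <- diff(d$two_theta_deg)
  if (diff(range(h)) > 0.01 * mean(h))
    stop("detect_peaks: 2-theta grid must be uniform within 1%")
  step <- mean(h)
  sw <- max(1L, as.integer(smooth_window))
  if (sw %% 2 == 0) sw <- sw + 1L
  y <- as.numeric(stats::filter(d$intensity, rep(1 / sw, sw), sides = 2))
  y[is.na(y)] <- d$intensity[is.na(y)]
  bw <- as.integer(round(baseline_deg / step))
  if (bw %% 2 == 0) bw <- bw + 1L
  bw <- max(3L, min(bw, length(y) - (1 - length(y) %% 2)))
  base <- stats::runmed(y, bw, endrule = "median")
  prom <- y - base
  n <- length(prom)
  is_max <- c(FALSE, prom[2:(n - 1)] > prom[1:(n - 2)] &
                     prom[2:(n - 1)] >= prom[3:n], FALSE)
  keep <- which(is_max & prom > min_prominence)
  data.frame(two_theta_deg = d$two_theta_deg[keep],
             height = d$intensity[keep], prominence = prom[keep])
}

#' Characteristic peak-position set
#'
#' @param name Set label (e.g. `"type_I"`).
#' @param positions_deg Characteristic 2-theta positions (degrees).
#' @param tolerance_deg Matching tolerance (default 0.2).
#' @return An object of class `peak_set`.
#' @export
peak_set <- function(name, positions_deg, tolerance_deg = 0.2) {
  if (tolerance_deg <= 0) stop("peak_set: tolerance must be positive")
  structure(list(name = name, positions_deg = sort(positions_deg),
                 tolerance_deg = tolerance_deg),
            class = "peak_set")
}

#' The two characteristic reflection sets of the emulsion matrix
#'
#' Type I: 3.9, 5.8, 7.8, 9.7, 13.6, 15.6, 19.6, 23.6 degrees 2-theta;
#' Type II: 4.7, 7.0, 9.4, 14.2, 16.5, 19.0, 33.6, 41.1 — both matched at
#' +/- 0.2 degrees.
#'
#' @return Named list of two [peak_set()] objects.
#' @export
xrd_peak_sets <- function() {
  list(type_I  = peak_set("type_I",  c(3.9, 5.8, 7.8, 9.7, 13.6, 15.6, 19.6, 23.6)),
       type_II = peak_set("type_II", c(4.7, 7.0, 9.4, 14.2, 16.5, 19.0, 33.6, 41.1)))
}

#' Classify a diffraction pattern against characteristic peak sets
#'
#' For each set, matches detected peak positions to characteristic
#' positions within the set tolerance; the set is declared present when at
#' least `min_fraction` of its characteristic positions are matched.
#'
#' @param positions_deg Detected peak positions (degrees).
#' @param sets List of [peak_set()] objects (default [xrd_peak_sets()]).
#' @param min_fraction Fraction of characteristic positions required
#'   (default 0.75).
#' @return data.frame per set: `set`, `n_matched`, `n_characteristic`,
#'   `fraction`, `present`, plus a `matches` attribute listing matched and
#'   missed positions.
#' @export
classify_pattern <- function(positions_deg, sets = xrd_peak_sets(),
                             min_fraction = 0.75) {
  detail <- list()
  out <- do.call(rbind, lapply(sets, function(s) {
    hit <- vapply(s$positions_deg, function(p)
      any(abs(positions_deg - p) <= s$tolerance_deg), logical(1))
    detail[[s$name]] <<- list(matched = s$positions_deg[hit],
                              missed = s$positions_deg[!hit])
    frac <- mean(hit)
    data.frame(set = s$name, n_matched = sum(hit),
               n_characteristic = length(hit), fraction = frac,
               present = frac >= min_fraction)
  }))
  rownames(out) <- NULL
  attr(out, "matches") <- detail
  out
}

#' Bragg d-spacing
#'
#' d = lambda / (2 sin(theta)) with theta half the diffraction angle;
#' converts a reflection position to a real-space repeat distance (e.g.
#' the ~4 Angstrom lamellar signal of surfactant phases).
#'
#' @param two_theta_deg Diffraction angle(s), 0 < 2-theta < 180 degrees.
#' @param wavelength_a Wavelength (Angstrom; default Cu K-alpha-1 1.5406).
#' @return d-spacing(s) in Angstrom.
#' @export
d_spacing <- function(two_theta_deg, wavelength_a = 1.5406) {
  if (any(two_theta_deg <= 0) || any(two_theta_deg >= 180))
    stop("d_spacing: 2-theta must lie in (0, 180) degrees")
  wavelength_a / (2 * sin(two_theta_deg * pi / 360))
}

#' Read a two-column diffractogram CSV
#'
#' Columns: `two_theta_deg`, `intensity`.
#' @param path CSV path.
#' @param wavelength_a Wavelength (default 1.5406).
#' @return A `diffractogram`.
#' @export
read_xrd_csv <- function(path, wavelength_a = 1.5406) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("two_theta_deg", "intensity") %in% names(df)))
    stop("read_xrd_csv: need columns two_theta_deg, intensity")
  diffractogram(df$two_theta_deg, df$intensity, wavelength_a)
}

#' Read a droplet-diameter CSV
#'
#' Columns: `batch_id`, `diameter_um`.
#' @param path CSV path.
#' @return Named list of diameter vectors, one per batch.
#' @export
read_droplets_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("batch_id", "diameter_um") %in% names(df)))
    stop("read_droplets_csv: need columns batch_id, diameter_um")
  lapply(split(df, df$batch_id), function(d) d$diameter_um)
}
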