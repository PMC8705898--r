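---
title: "Extended pharmaceutical equivalence of topical semisolids: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended pharmaceutical equivalence of topical semisolids: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topeq)
```

## The problem

Under the EMA draft guideline on quality and equivalence of topical
products, claiming equivalence between two semisolid formulations (or, as
in a batch-consistency study, between two batches of the same product)
requires agreement at several levels: quantitative physicochemical and
microstructure attributes, in vitro release through a synthetic membrane
(IVRT), and — for complex formulations such as emulsions — in vitro
permeation through excised human skin (IVPT). Each level is judged by a
90% confidence interval of a batch ratio against a fixed acceptance range:

* physicochemical / microstructure parameters: 90–110%,
* IVRT release parameters (release constant K, cumulative amount at 6 h
  Q6h): 90–111%,
* IVPT permeation parameters (steady-state flux Jss, cumulative amount at
  24 h Q24h): 80–125%.

Equivalence requires the *whole* interval inside the range; a negative
(discriminatory) control must place its whole interval *outside*.
`topeq` implements this pipeline end to end, from raw Franz-cell sampling
records to verdict tables, together with seeded generators for every
input class so that each statistical engine can be validated against
known truth.

## From sampling records to cumulative profiles

A vertical (Franz) diffusion cell is sampled periodically: a volume
$V_s$ is withdrawn from the receptor (volume $V_r$) and replaced with
fresh medium. The drug released up to draw $n$ is therefore the current
receptor content plus everything carried away earlier:

$$Q_n = \frac{C_n V_r + \sum_{i<n} C_i V_s}{A},$$

with $A$ the diffusion area. This is the universal Franz-cell mass
balance; the correction is on by default (`correct_sampling = TRUE` in
`cumulative_profile()`) and can be switched off for data already
corrected upstream. The canonical internal units are µg, cm² and h;
ng/mL inputs (the usual IVPT scale) are converted on entry. Q is *not*
forced to be monotone — assay noise legitimately produces local
decreases, and silently monotonizing would bias the fits.

If a time-zero row with zero concentration is absent it is not
synthesized: the fits below exclude $t = 0$ anyway.

## Release kinetics (IVRT)

Release from a semisolid into a sink-condition receptor follows Higuchi
kinetics: $Q(t) \approx K\sqrt{t}$. `higuchi_fit()` regresses $Q$ on
$\sqrt{t}$ by OLS over all positive-time points (a fit window can
restrict this, e.g. to drop an early burst). Two deliberate choices:

* **The intercept is estimated, not forced to zero.** Burst release or a
  short equilibration lag otherwise biases the slope; a `intercept =
  FALSE` flag restores the forced-zero fit for sensitivity analyses.
* **Q6h is the measured (or linearly interpolated) 6 h value**, not the
  regression prediction at $\sqrt{6}$. Reported Q6h summaries carry SDs
  independent of the fit, which is only consistent with the sampled
  reading; the fitted alternative is available from the returned object
  (`K`, `intercept`).

Method validation follows the guideline's four parts: linearity of K and
Q6h across three dose strengths (pass at $r^2 > 0.90$), intermediate
precision (per-operator and pooled CV < 10%, pooled CV computed from raw
replicates, not from operator means), discriminatory power (the whole
90% ratio CI of a deliberately altered formulation must fall outside
90–111%), and robustness (one-way ANOVA of each modified operating
condition against the standard runs, flagged at $p < 0.05$; the paper
trail of a typical study uses 3 replicates per modified level, so the
two-group layout is the default).

## Permeation kinetics (IVPT)

Skin replicates first pass a TEER integrity gate: kept only when
resistance is strictly above 2000 Ω. Cumulative permeation is then
linear after a lag: `flux_fit()` regresses $Q$ on $t$ over a
steady-state window, giving $J_{ss}$ (slope) and lag time
($-\text{intercept}/\text{slope}$, only defined for a positive slope;
negative lags are reported and flagged, not truncated).

**Window rule.** Published permeation studies rarely state their
regression window. The default here is reproducible: among trailing
contiguous windows (ending at the last sampling time) of at least 5
points, take the one maximizing $r^2$, ties to the longer window. Any
explicit window overrides this.

The replicate → donor → arm hierarchy is fixed: within-donor replicates
are collapsed by geometric mean first (`donor_geomean()`), and all
between-batch statistics operate on the n-donor list. No mixed-effects
model is fitted — with 6 donors × 2 replicates the hierarchical
collapse is the standard, transparent choice.

Equivalence uses the standard bioequivalence construction: a two-sample
Welch interval on log-transformed donor means, exponentiated
(`ci_ratio_log()`), judged against 80–125%. Mass balance closes the
loop: receptor + skin-retained + residual drug as a percentage of the
applied dose, cells flagged outside 90–110%.

## The confidence-interval engines

For summaries $(\bar X, s, n)$ per arm, the difference interval is

$$(\bar X_t - \bar X_r) \pm t_{1-\alpha/2,\,\mathrm{df}}
  \sqrt{s_t^2/n_t + s_r^2/n_r}, \qquad \alpha = 0.10,$$

with Welch–Satterthwaite df by default (pooled df available; at the
sample sizes of these studies the two agree to printed precision). The
*ratio* interval used for IVRT and physicochemical comparisons is this
interval shifted by $\bar X_r$ and divided by $\bar X_r$ — equivalently,
the standard error is scaled by the reference mean. A literal reading
that adds an absolute-scale standard error to a dimensionless ratio is
dimensionally inconsistent; the reference-mean-scaled form is adopted
because it exactly reproduces published discriminatory-power intervals
from their printed batch summaries, and it makes the identity

$$\mathrm{CI}_\text{ratio} = \frac{\bar X_r + \mathrm{CI}_\text{diff}}{\bar X_r}$$

hold to machine precision (this identity is asserted in the test
suite). `bootstrap_ci()` provides a seeded nonparametric percentile
alternative for small-sample sensitivity analyses.

Acceptance ranges are registered as *closed* intervals on the ratio
scale; `range_check()` returns exactly one of `within` / `outside` /
`straddles`, with boundary contact counting as within.

`alpha` is fixed at 0.10 by default (the guideline's 90% CI) and is
configurable only for sensitivity analyses.

## Rheology descriptors

Five descriptors summarize a flow loop (up ramp 0→300 s⁻¹, hold, down
ramp) and an oscillatory stress sweep (0.1–1000 Pa at 1 Hz):

* **η₃₀₀** — stress/rate at 300 s⁻¹, from the hold-segment mean when
  present, else interpolated on the up ramp. Viscosity is treated in
  Pa·s throughout (instrument exports sometimes label the column "Pa";
  the numbers are unaffected, only the unit label differs).
* **RTLA** — relative thixotropic loop area,
  $100\,(S_\text{asc} - S_\text{desc})/S_\text{asc}$, trapezoidal areas
  in stress–shear-rate coordinates over the sampled points only (no
  extrapolation to 0 or 300 s⁻¹). 0 for reversible curves, invariant to
  uniform stress rescaling.
* **Yield stress** — the sweep's linear-viscoelastic plateau is the
  first run of ≥ 4 consecutive points whose G′ spread is < 5% of their
  mean; yield is where G′ first drops more than 10% below the plateau
  mean, log-interpolated between bracketing points. The guideline names
  the parameter but no extraction rule; this deviation definition is the
  default and a G′ = G″ crossover alternative is available
  (`method = "crossover"`).
* **G\*** and **δ** — $\sqrt{G'^2 + G''^2}$ and
  $\operatorname{atan}(G''/G')$ in degrees, averaged over the plateau.

Descriptor comparisons go through the same ratio-CI engine against
90–110%.

## Microstructure

Droplet diameters are summarized by mean, sample SD and histogram, and
compared by ratio CI; because droplet sizes are typically right-skewed,
an Anderson–Darling normality screen (case 3, small-sample-corrected
statistic, via `nortest`) attaches a warning when the normal-theory
interval's assumption fails — the screen rejecting while the guideline
presumes normality is itself a reportable finding.

Diffractograms are processed with moving-average smoothing, a rolling-
median baseline over a 2° window (robust against the amorphous hump of
a semisolid), and prominence-filtered local maxima. Detected positions
are classified against the two characteristic reflection sets of the
emulsion matrix (`xrd_peak_sets()`, ±0.2° matching); a set is declared
present when ≥ 75% of its positions match — a package choice, since
published pattern "deconvolution" procedures are rarely specified.
`d_spacing()` converts angles via Bragg's law; the strong 21.2°
reflection corresponds to ≈ 4.19 Å, a lamellar repeat, with its 44.1°
harmonic at half that spacing.

## The synthetic-data generators

Every input class can be generated with a mandatory seed
(bit-reproducible), with defaults that emulate a three-batch pilot study
of a 0.025% w/w capsaicin emulsion:

* `gen_release()`: $q(t) = K\sqrt t + \varepsilon$, K ≈ 28
  µg·h⁻¹ᐟ²·cm⁻², additive Gaussian noise (SD 1 µg/cm²) plus a lognormal
  between-cell K dispersion (CV 8%) — reproducing the tight
  single-digit release CVs such methods validate to. Crucially the
  generator *inverts the sampling correction* and emits concentration
  records, so the pipeline's correction path is always exercised.
* `gen_permeation()`: zero-order flux after a 2 h lag, Jss ≈ 15
  ng·h⁻¹·cm⁻², with a multiplicative lognormal hierarchy — donor CV 0.5
  (permeation SDs of 50–60% of the mean are typical of human skin),
  replicate CV 0.15, 5% measurement noise — and simulated TEER with a
  configurable failing fraction. All lognormal effects are
  mean-corrected ($-\sigma^2/2$) so the generated parameters are
  unbiased targets for recovery tests.
* `gen_flow_curve()`: Herschel–Bulkley up ramp, down ramp scaled to
  $(1-\text{thixo fraction})$ so RTLA has a closed-form truth;
  `gen_osc_sweep()`: G′ plateau with power-law post-yield decay at a
  known critical stress and constant phase angle.
* `gen_droplets()`: lognormal with moment-matched mean/SD;
  `gen_diffractogram()`: Gaussian reflections over a Gaussian hump with
  counting noise, on a 0.05° grid — fine enough to resolve the ±0.2°
  matching tolerance.

`study_scenario()` bundles the full design (3 IVRT batches × 12
replicates; 2 IVPT batches + a double-strength negative control × 6
donors × 2 replicates) and `simulate_study()` materializes it.

What the generators do *not* emulate: dose depletion and sink-condition
violations, skin-site heterogeneity within a donor, membrane fouling,
instrument drift, and correlated assay error. Passing tests therefore
demonstrate that the estimators and interval engines are correct under
the stated stochastic model, not that any particular laboratory dataset
satisfies that model.

## Numerical choices and degenerate inputs

* $r^2$ is computed as $1 - \mathrm{RSS}/\mathrm{TSS}$ with a guard that
  returns 0 when the response is numerically constant (round-off-scale
  TSS makes the naive ratio meaningless).
* `flux_fit()` treats a slope at round-off scale as flat (warning, lag
  `NA`) rather than producing astronomical lag times.
* Interpolation never extrapolates; out-of-range queries error.
* Degenerate ANOVA variance yields `NA` p-values with a warning rather
  than a spurious verdict.
* Geometric means require positivity; offending donors are excluded
  with a named diagnostic.
* TEER uses a strict inequality at the cut-off ("above" the threshold
  indicates suitability).

## Validation problem sizes

The test suite validates the engines at sizes chosen to balance
Monte-Carlo resolution against run time: 500-replicate recovery studies
for K and Jss (bias asserted within 3 Monte-Carlo SEs), 2000-replicate
coverage of the log-ratio CI at n = 6 donors (90% ± 3 points),
2000-replicate size check of the Anderson–Darling screen, a 4000-dataset
type-I-error check of the robustness ANOVA, and a 200 000-draw
parametric bootstrap oracle for the ratio interval. Published summary
tables that are reproducible from printed means/SDs/n (batch ratios, the
discriminatory-power CI, operator CVs, geometric-mean ratios) are
asserted exactly at printed precision; published CI *endpoints* computed
from raw replicate data that was never published are not reproduction
targets — the property-based checks above stand in for them.

## Known limitations

* The package compares batches; it does not model within-batch aging
  (rheological descriptors drift strongly over months), though the
  descriptor tables make such comparisons easy.
* No mixed-effects or finite-dose mechanistic modeling; the hierarchy
  is collapsed by geometric means as the guideline workflow does.
* The SUPAC-SS nonparametric interval and Mahalanobis-distance
  approaches, and f2 similarity, are out of scope.
* XRD classification matches characteristic positions; it does not
  deconvolute overlapping reflections or quantify phases.
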