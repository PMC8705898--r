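# topeq

Extended pharmaceutical equivalence analysis for topical semisolid
products (creams, emulsions, gels), following the EMA draft guideline on
quality and equivalence of topical products. `topeq` is aimed at
formulation and regulatory scientists who need to compare batches of a
semisolid — or a test product against a reference — across the
guideline's three tiers:

* **IVRT** (in vitro release through a synthetic membrane in Franz
  diffusion cells): Higuchi release constant *K* and cumulative amount
  at 6 h (*Q6h*), judged by 90% confidence intervals of the batch ratio
  against **90–111%**;
* **IVPT** (in vitro permeation through excised human skin):
  steady-state flux *Jss* and cumulative amount at 24 h (*Q24h*),
  collapsed replicate → donor by geometric means, log-scale Welch
  intervals against **80–125%**, plus TEER integrity gating and mass
  balance;
* **microstructure and rheology**: droplet-size statistics with an
  Anderson–Darling normality screen, XRD peak detection / Type I–II
  pattern classification / Bragg d-spacing, and the five rheological
  descriptors (η₃₀₀, relative thixotropic loop area, oscillatory yield
  stress, G\*, phase angle δ), judged against **90–110%**.

The statistical core is the pair of guideline interval engines. For arm
summaries (X̄, s, n):

    difference:  (X̄_t − X̄_r) ± t_{1−α/2, df} · √(s_t²/n_t + s_r²/n_r)
    ratio:       the same interval shifted by X̄_r and divided by X̄_r

with α = 0.10 and Welch–Satterthwaite df (pooled optional), and, for
permeation, the exponentiated Welch interval on log donor means. A
seeded nonparametric bootstrap interval is available as a sensitivity
alternative. Verdicts (`within` / `outside` / `straddles`) are taken
against closed acceptance ranges.

The package also ships seeded synthetic-data generators for every input
class (Franz-cell concentration records, donor hierarchies with
lognormal variability, thixotropic flow loops, oscillatory sweeps,
droplet samples, diffractograms), so the whole pipeline is testable and
its operating characteristics measurable without laboratory data —
generators emit raw *concentration* records that are pushed back through
the sampling-replacement correction, never precomputed profiles.

## Worked example

Summary-level equivalence of two batches' Q6h (n = 12 replicates each),
straight from their means and SDs:

```r
library(topeq)
equivalence_report(group_summary(57.27, 4.08, 12),
                   group_summary(56.69, 8.88, 12),
                   "ivrt_90_111", parameter = "Q6h (ug/cm^2)")
#> Equivalence report: Q6h (ug/cm^2)
#>   test: mean 57.2700, SD 4.0800, n 12
#>   ref:  mean 56.6900, SD 8.8800, n 12
#>   ratio 101.02%, 90% CI [0.9232, 1.0973], df 15.45
#>   vs ivrt_90_111 [0.9, 1.11]: within
```

The batch ratio is 1.010 (101.02%) and the whole 90% CI sits inside
90–111%: these two batches release equivalently. A full raw-data
workflow — simulate a three-batch study (12 Franz cells per batch),
rebuild corrected cumulative profiles, fit Higuchi kinetics per cell and
compare batches:

```r
sc  <- study_scenario(seed = 42)
sim <- simulate_study(sc)
st  <- ivrt_study(sim$ivrt, ref = "batch2")
st$equivalence
#>         comparison parameter n_test mean_test sd_test n_ref mean_ref sd_ref
#> 1 batch1 vs batch2         K     12     29.44   2.568    12    29.43  2.715
#> 2 batch1 vs batch2        q6     12     71.15   5.569    12    71.50  5.918
#> 3 batch3 vs batch2         K     12     28.64   1.952    12    29.43  2.715
#> 4 batch3 vs batch2        q6     12     69.84   4.789    12    71.50  5.918
#>    ratio  lower upper status
#> 1 1.0004 0.9374 1.063 within
#> 2 0.9951 0.9387 1.051 within
#> 3 0.9731 0.9165 1.030 within
#> 4 0.9767 0.9238 1.030 within
```

Each row is one batch comparison for one release parameter: the fitted
per-cell parameters are summarized per batch, the ratio CI is computed,
and `status` is the guideline verdict. `ivpt_study()`,
`rheology_study()` and `microstructure_study()` provide the analogous
end-to-end paths for the other tiers; `write_report_json()` emits
machine-readable reports.

See the vignette (`vignettes/topical-equivalence.Rmd`) for the models,
parameter choices and validation design.

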