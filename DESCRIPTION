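Package: topeq
Title: Extended Pharmaceutical Equivalence Analysis for Topical Semisolid Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical workflow for batch-to-batch and test-versus-reference
    equivalence of topical semisolid products under the EMA draft guideline on
    quality and equivalence of topical products. Converts raw Franz diffusion
    cell sampling records into sampling-replacement-corrected cumulative
    release profiles; estimates Higuchi release kinetics (IVRT) and
    steady-state skin flux with lag time (IVPT); computes 90% confidence
    intervals for differences and ratios of batch means (Welch or pooled
    degrees of freedom) and log-scale ratio intervals for donor geometric
    means, with verdicts against the 90-110%, 90-111% and 80-125% acceptance
    ranges; derives rheological descriptors (viscosity at 300 1/s, relative
    thixotropic loop area, oscillatory yield stress, complex modulus, phase
    angle) and microstructure descriptors (droplet-size statistics with
    Anderson-Darling normality screening, X-ray diffraction peak detection and
    pattern classification, Bragg d-spacing). Includes seeded synthetic-data
    generators for every input class so the full pipeline can be exercised and
    validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    nortest,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
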