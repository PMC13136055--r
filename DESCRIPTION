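Package: artga
Title: Gestational Age Dating and Pregnancy Duration Analysis for ART
    and Spontaneous Pregnancies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing gestational-age (GA) dating scales in
    pregnancies conceived by assisted reproductive technology (ART) and
    spontaneously, and for censoring-aware analysis of pregnancy duration.
    Implements ART-based dating with a configurable follicular-phase
    constant (14 or 15 days), propagation of registry-recorded GA to any
    calendar date, estimated date of delivery on the 283-day calibrated
    scale, pairwise agreement statistics between ultrasound and ART-based
    dating, a from-scratch Kaplan-Meier product-limit estimator with
    Greenwood variance, survival medians with parametric Monte Carlo
    confidence intervals, cause-specific cumulative incidence
    (Aalen-Johansen) for competing risks, censoring-strategy comparisons,
    and a synthetic birth-registry generator that emulates the statistical
    structure of national registry data so the whole pipeline is testable
    without restricted data access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
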