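Package: pevconv
Title: Conversion-Rate Kinetics of Position-Effect Variegation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies epigenetic switching at variegating loci with a
    two-state per-generation conversion model. Provides the deterministic
    recurrence and its closed-form solution, equilibrium and
    time-to-equilibrium analysis, stochastic branching simulation of
    single-cell-founded mini-cultures, least-squares estimation of
    silent-to-active and active-to-silent conversion coefficients from
    dual-selection time courses with bootstrap intervals, classification of
    loss/gain of silencing versus loss/gain of epigenetic stability, a
    synthetic assay-data generator (colony plating counts, OD-derived
    generation numbers, per-clone FACS fractions), and a small command-line
    interface over tab-separated time-course tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
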