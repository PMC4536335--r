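Package: synergysig
Title: Median-Effect Synergy Analysis, Gene-Signature Screening and
    Survival Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for constant-ratio drug-combination studies and their
    downstream genomics: normalization of plate viability data, fitting of
    the two-parameter median-effect dose-effect model, Chou-Talalay
    combination-index computation and classification for mutually
    nonexclusive agents, a Pearson correlation screen of gene expression
    against IC50 with Benjamini-Hochberg false-discovery-rate control,
    first-principal-component signature scoring with median
    dichotomization, Kaplan-Meier estimation and the two-group log-rank
    test, and immunohistochemistry product scoring
    (intensity x cellularity). Includes seeded synthetic-data generators
    that emulate each input with known ground truth, so the entire
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    yaml
Config/testthat/edition: 3
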