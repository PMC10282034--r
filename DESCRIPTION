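Package: phenomr
Title: Phenome-Wide Two-Sample Mendelian Randomisation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for phenome-wide two-sample Mendelian
    randomisation screens of causal risk factors on a binary outcome such as
    primary open angle glaucoma. Provides GWAS summary-statistic input and
    output in a canonical tab-separated dialect, adaptive p-value-ladder
    instrument selection, LD-proxy substitution and PLINK-style clumping,
    allele harmonisation with palindromic-variant handling, Steiger
    directionality filtering, robust causal estimators (fixed and
    multiplicative-random-effects inverse-variance weighting, MR-Egger with
    intercept and I2_GX diagnostics, weighted median, weighted mode), radial
    MR outlier detection, Cochran's Q and leave-one-out quality control,
    Benjamini-Hochberg false-discovery-rate control with a five-way
    significance criterion, multivariable MR with conditional F statistics
    and adjusted Q, a rare-variant collapsing burden test, and a synthetic
    GWAS generator with known ground truth for calibration and recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
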