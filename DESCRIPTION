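Package: panoxia
Title: Pan-Cancer Expression, Hypoxia and Tumor-Microenvironment Association Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pan-cancer association analysis of target gene panels
    (such as the VEGF angiogenesis family) against tumor hypoxia, prognosis,
    immune subtype, tumor microenvironment and drug response. Implements
    per-sample signature scoring (a binary +1/-1 median-split hypoxia score
    over a pooled multi-cancer cohort, and a rank-weighted single-sample
    enrichment score with exponent alpha = 0.25 used for stromal, immune and
    combined ESTIMATE-style scores), tumor-versus-normal differential
    expression with the exact Wilcoxon signed-rank test, median-split
    Kaplan-Meier and log-rank survival analysis with univariate Cox
    regression, Kruskal-Wallis immune-subtype and tumor-stage comparisons,
    Benjamini-Hochberg correction throughout, KNN imputation of drug-activity
    matrices with expression-drug Pearson correlation, and a synthetic-cohort
    generator with planted effects for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
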