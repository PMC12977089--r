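Package: prsbrainmap
Title: Polygenic Risk Score Association Scans, Brain-Map Concordance and
    Mendelian Randomization for Regional Brain Morphology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links polygenic risk scores (PRS) for neuropsychiatric
    disorders to regional brain morphology. Provides covariate
    residualization with rank-based inverse normal transformation,
    per-disease-per-region linear association scans with eigenvalue-based
    effective-test Bonferroni tiers, comparison of genetic-risk Cohen's d
    brain maps against case-control (ENIGMA-style) maps via exact binomial
    sign concordance and permutation-null spatial correlation with
    Benjamini-Hochberg adjustment, a bidirectional two-sample Mendelian
    randomization suite (IVW, Egger, weighted median, weighted mode, and a
    GSMR-style HEIDI outlier filter) with sensitivity analyses, and an
    exact binomial quadrant enrichment test for diagnosed individuals with
    high genetic risk and small brain measures. A synthetic-data module
    generates cohorts, effect-size maps and paired GWAS summary statistics
    with known ground truth so the full pipeline is testable without
    restricted individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
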