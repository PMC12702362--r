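Package: serpinscreen
Title: Deep Mutational Scanning of Serpin Latency and Protease Inhibition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-timepoint phage-display deep
    mutational scanning screens of metastable serpins such as plasminogen
    activator inhibitor-1 (PAI-1). Provides a synthetic screen generator
    with an exponential latency-decay selection model, a negative-binomial
    variant enrichment engine (median-of-ratios normalization, moment
    dispersion estimation, Wald tests, Benjamini-Hochberg FDR), positional
    mutational-acceptance smoothing with LOWESS and stabilizing/
    destabilizing region calling, stratified comparison against variant
    effect predictor and protein stability predictor tables using linear
    mixed models with random positional effects, and purifying-selection
    analyses of per-position conservation scores (regressions, median
    quadrant segmentation, one- and two-way ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
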