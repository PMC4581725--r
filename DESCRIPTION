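Package: epistage
Title: Stage-Wise Closed Testing for Pairwise Genetic Interactions in
    Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Large-scale detection of pairwise genetic interactions
    (epistasis) in case-control genotype data. Per-pair generalized linear
    models of two-locus penetrance are fitted on five link scales
    (additive and multiplicative penetrance, genetic heterogeneity,
    additive and multiplicative odds), and variant pairs are tested by a
    stage-wise closed-testing procedure that rejects a sequence of nested
    null models (no association, single main effect, double main effect)
    before the final scale-invariant interaction test. Both a static
    procedure with a-priori multiple-testing corrections and an adaptive
    procedure driven by per-stage rejection counts are provided, together
    with comparison methods (direct logistic interaction test, marginal
    and linkage-disequilibrium based screens, LD-contrast tests), a
    two-locus penetrance-model simulation framework with heritability
    calibration, family-wise error rate and power experiment drivers, and
    PLINK/TSV genotype input with standard quality-control filters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
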