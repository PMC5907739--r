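Package: picv
Title: Proportional Instance Cross Validation for SNP-SNP Interaction
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Train/test splitting that preserves the joint distribution of
    the two-locus genotype (proportional instance cross validation, PICV)
    for epistasis analyses in case-control genetic association studies,
    together with a full evaluation harness: penetrance-table epistasis
    models under Hardy-Weinberg equilibrium, GAMETES-style balanced
    case-control data simulation, logistic main-effect and interaction
    models with likelihood-ratio testing, classification performance
    measures with explicit undefined states, and one-sided two-sample
    Kolmogorov-Smirnov comparison of train/test consistency between PICV
    and traditional random cross validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
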