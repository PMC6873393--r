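Package: logiclm
Title: Interpretable Rule-Based Classification of Expression Profiles with
    Diagnostic Meta-Analysis
Version: 0.1.0
Authors@R:
    person("logiclm", "maintainers", email = "maintainers@logiclm.dev",
           role = c("aut", "cre"))
Description: Trains interpretable threshold-rule classifiers on gene
    expression matrices in the style of the Logic Learning Machine:
    supervised entropy-based discretization, inverse only-one binarization
    (latticization), greedy monotone implicant generation, and conversion of
    implicants to intelligible "if ... then ..." rules with covering, error
    and relevance measures.  Also provides the companion diagnostic-accuracy
    toolkit: sensitivity, specificity, Youden index, Cohen kappa (binary and
    multi-class), diagnostic odds ratios with continuity correction,
    Mantel-Haenszel pooling across categories, fixed-effect summary ROC
    meta-analysis (sOR, sAUC, confidence intervals), a leave-one-out
    cross-validation harness with the published tuning grids, and a
    synthetic expression-data generator with planted threshold rules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
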