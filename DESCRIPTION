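Package: segtrain
Title: Annotation-Guided Training of Copy Number Segmentation Models
Version: 0.1.0
Authors@R:
    person("Repository", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Supervised selection of the degree of smoothness in DNA copy
    number profile segmentation.  Provides exact penalized least-squares
    changepoint models (dynamic-programming segmentation with Lavielle- and
    PELT-style penalties) and an exact one-dimensional fused-lasso smoother,
    together with a breakpoint-annotation error and ROC framework, global
    and per-profile smoothness training with explicit tie-breaking rules,
    leave-one-annotation-out and fold-based cross-validation protocols, and
    a seeded synthetic profile generator emulating both annotation
    protocols, so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
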