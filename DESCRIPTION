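Package: citrusRL
Title: Lightweight Citrus Detection Networks and Orchard Yield Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles and trains lightweight one-stage citrus detectors built
    from re-parameterizable convolution blocks (RepConv), ELAN-style
    split-aggregate feature blocks (RGCSPELAN) and a shared-convolution,
    group-normalized detection head (LSCD), with exact parameter and FLOP
    accounting for the published model variants. Includes a synthetic orchard
    scene generator (three phenological classes: flower, green fruit, orange
    fruit) with YOLO-format labels, standard detection metrics
    (precision, recall, AP at IoU 0.5, F1), an SGD training loop with
    task-aligned assignment, and two-stage count-to-yield regression models
    with error-rate accounting for tree-level fruit counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
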