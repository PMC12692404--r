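Package: ptmlfbtd
Title: Perturbation-Theory Machine Learning with Fragment-Based
    Topological Design for Multi-Condition Activity Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes bond-based spectral moments, Kier-Hall valence
    connectivity indices and bond connectivity indices from SMILES,
    fuses them with experimental-condition labels through a Box-Jenkins
    moving-average scheme into multi-label perturbation descriptors,
    trains a shallow multilayer-perceptron classifier of
    anti-proliferative activity with an applicability-domain bounding
    box, and interprets the fitted model fragment-wise (input
    sensitivities, tendency-of-variation tables, multi-cell activity
    verdicts, druglikeness screening). Includes a synthetic assay-data
    generator with a planted descriptor-activity relationship for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
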