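Package: tastedyn
Title: Encoding Dynamics in Rat Gustatory Cortices During Taste Categorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing single-neuron and population encoding
    dynamics in two-alternative taste (water versus sucrose)
    categorization sessions. Implements sliding-window auROC screening of
    stimulus-, choice- and outcome-encoding neurons with permutation
    significance and choice-probability disambiguation; sequentiality
    indices (peak entropy, temporal sparsity) over selectivity matrices
    with split-half reproducibility tests; resampled, cross-validated
    pseudo-population SVM decoding with confusion-pattern analysis and a
    lick-warped behavioural control; power-law psychometric fitting and
    single-neuron neurometric curves; and condition-averaged PCA
    population trajectories. Ships an inhomogeneous-Poisson session
    simulator with known ground truth so every stage of the pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
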