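Package: hubshift
Title: Longitudinal Resting-State Functional-Connectivity Networks and
    Brain Hub-Shift Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline from region-wise BOLD time series to
    thresholded functional-connectivity graphs, degree-centrality hub maps,
    longitudinal change matrices, and motor-subnetwork hub-shift statistics,
    as used in longitudinal rodent resting-state fMRI studies. Includes
    temporal bandpass filtering, Pearson connectivity, strength/density/degree
    graph measures, node-wise paired tests and mixed repeated-measures
    comparisons, primary-motor-cortex seeded subnetwork extraction,
    mean + k*SD hub identification, and a deterministic synthetic multi-subject
    BOLD cohort generator with planted, time-shifting hub structure.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
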