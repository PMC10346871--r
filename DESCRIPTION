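Package: covidsa
Title: Hybrid Coronavirus-Optimization and Simulated-Annealing Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Wrapper feature selection for high-dimensional activity-recognition
    feature tables using a hybrid of the Coronavirus Disease Optimization
    Algorithm (COVIDOA), a population metaheuristic whose replication operator
    mimics ribosomal frameshifting, and a simulated-annealing refinement stage
    seeded with the population optimum. Candidate feature subsets are bit
    masks scored by a wrapper objective combining the error of a native
    k-nearest-neighbour classifier with a subset-size penalty. Includes
    readers for the UCI-HAR whitespace-separated layout and generic CSV,
    a synthetic multi-class generator with informative, redundant and noise
    features, confusion-matrix evaluation metrics, and multi-run aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
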