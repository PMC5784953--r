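Package: pathwaybench
Title: Benchmarking Topology-Based Pathway Analysis Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A common pathway-graph data model and fresh implementations of seven
    topology-based pathway analysis methods (SPIA, PRS, CePa-ORA, TAPPA,
    TopologyGSA, Clipper and DEGraph) for detecting differentially expressed
    pathways between two groups from log2 gene expression data, together with a
    synthetic expression-data generator and a suite of controlled benchmark
    experiments (null calibration and type-I error, sample- and pathway-size
    sensitivity, single-gene / gene-set / motif overexpression influence
    profiling, topology ablation and pre-processing contrasts). Results are tidy
    tibbles with broom-style tidiers and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
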