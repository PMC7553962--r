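Package: csgcn
Title: Condition-Specific Gene Co-Expression Networks and Gene-Set
    Biomarker Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds condition-specific gene co-expression networks from a
    labeled expression matrix by Gaussian-mixture deconvolution of every
    gene pair's sample space, Spearman correlation within sample clusters,
    and random-matrix-theory thresholding; detects link-community modules;
    tests edges and modules for sample-label enrichment (Fisher's exact
    test with Hochberg correction) to extract region-specific mini-networks;
    screens the resulting gene sets as biomarkers with a feedforward
    neural-network classifier against size-controlled random gene-set
    nulls; decomposes significant sets into candidate genes by
    combinatorial subset search; and tests gene sets for somatic-mutation
    enrichment by resampling. Includes a synthetic-data generator with
    planted region-specific modules so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    limma,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
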