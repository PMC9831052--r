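Package: netshy
Title: Topology-Aware Summarization of Network Modules via Laplacian-Weighted PCA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Subject-level summarization of weighted biological network modules.
    Implements NetSHy, which applies principal component analysis to the node
    profile matrix right-multiplied by the graph Laplacian, so that the
    resulting module score reflects both the measured profiles and the module
    topology. Also provides the conventional eigengene (plain first principal
    component) and hub-node baselines, a Gaussian graphical model simulation
    engine in which the network adjacency seeds the precision matrix, evaluation
    criteria (correlation with a phenotype and proportion of variance explained,
    each relative to an optimal baseline computed from the noise-free profiles),
    a subsampling robustness protocol, and a bootstrap test comparing the
    phenotype correlations of two summarizations.
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
    igraph,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
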