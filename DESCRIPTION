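Package: sparccnet
Title: Microbial Co-Occurrence Networks from Compositional Abundance Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers microbial co-occurrence networks from OTU/ASV relative
    abundance tables using the SparCC compositional correlation estimator
    (log-ratio variation matrix, basis variances, iterative strong-pair
    exclusion, Dirichlet resampling, Monte-Carlo permutation p-values, and
    optional HDF5 disk-backed intermediates), embeds and clusters taxa with
    UMAP and a native HDBSCAN implementation including GLOSH outlier scores,
    and characterises the resulting signed networks: global topology and
    small-world index against matched random, small-world and scale-free
    nulls, degree-distribution CCDF comparison, structural-balance triad
    census, percolation robustness simulation, Louvain community reports and
    per-node centralities. Includes a synthetic-community generator with
    planted basis correlations for benchmarking, a single-command pipeline,
    and a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    dplyr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    uwot,
    vegan,
    withr,
    yaml
Suggests:
    optparse,
    rhdf5,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
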