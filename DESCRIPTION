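Package: modulomics
Title: Multi-Omic Sample Module Discovery with Per-Module Omic Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers disjoint modules of samples in multi-omic datasets,
    where each module covers only the subset of omics in which its samples are
    mutually similar. One signed, edge-weighted sample graph is built per omic
    (by consensus co-clustering over resampled runs, or from a Gaussian mixture
    model), and the summed intra-module edge weight is maximised by a greedy
    local search with seed finding, merge/split/omic actions and restarts,
    followed by an empirical significance filter. Handles samples measured in
    only a subset of omics, classifies new samples into existing modules, and
    ships a synthetic multi-omic data generator with planted modules, per-module
    omic coverage and outliers, plus Adjusted Rand Index and cross-validation
    evaluation utilities.
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
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
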