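Package: scaffscape
Title: Scaffold Architecture Analysis of Compound Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes compound libraries into Bemis-Murcko frameworks, graph
    frameworks, rings, ring assemblies, bridge assemblies, linkers and side
    chains; builds hierarchical Scaffold Tree chains by prioritized iterative
    ring removal; quantifies scaffold diversity with frequency censuses and
    cumulative scaffold frequency curves; compares libraries by circular
    fingerprint Tanimoto overlap at descending similarity cutoffs; clusters
    scaffolds by maxmin diversity selection and renders frequency-weighted
    squarified treemaps. Ships a synthetic library generator with planted
    ground truth so every pipeline stage can be validated without access to
    proprietary compound databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    Matrix,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    ggplot2,
    rlang,
    withr,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
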