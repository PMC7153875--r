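Package: socmux
Title: Multiplex Social Network Analysis of Focal-Sampled Animal Groups
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and analysing multiplex (multilayer) social
    networks from focal-sampling behavioural observations of small animal
    groups. Parses focal records and sampling effort, computes normalized
    dyadic interaction indices per interaction type, assembles node-aligned
    weighted undirected multiplex networks with unit interlayer coupling,
    and computes per-layer eigenvector centrality, multiplex eigenvector
    versatility, and edge overlap. Implements structural reducibility:
    Laplacian density matrices, von Neumann graph entropy, Jensen-Shannon
    distances between layers, Ward agglomeration, and the relative-entropy
    curve that decides which layers can be aggregated without losing
    non-redundant structural information. Includes a synthetic
    focal-sampling generator with tunable cross-layer redundancy for
    testing structure recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
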