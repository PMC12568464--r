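Package: topoEntropy
Title: Degree-Based Topological Indices and Shannon Edge-Entropy of
    Molecular Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes the classical degree-based topological indices of
    hydrogen-suppressed molecular graphs (first and second Zagreb, general
    and ordinary Randic, hyper-Zagreb, sum-connectivity and general
    sum-connectivity, geometric-arithmetic, atom-bond connectivity,
    harmonic) together with the Shannon entropy of each index's edge
    contribution distribution.  Indices and entropies are evaluated either
    on explicit graphs or directly on degree-pair edge partitions (joint
    degree matrices).  Includes closed-form partition models and index
    evaluators for two fractal molecular families -- the kekulene
    cycloarene series and a terpyridine-metal Sierpinski triangle series --
    a verified constructor for the kekulene C48 skeleton, realization of
    simple graphs from feasible edge partitions, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
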