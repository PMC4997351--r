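Package: mucinEvol
Title: Evolutionary Analysis of Copy-Number Variable Subexonic Mucin Repeats
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the evolution of copy-number variable
    subexonic tandem repeats in mucin-type coding sequences. Detects
    in-frame PTS (proline/threonine/serine-rich) repeat units in coding
    sequences, partitions pairwise repeat divergence into synonymous and
    nonsynonymous components by Nei-Gojobori pathway averaging, clusters
    repeat units and scores recurrent (species-private) expansion.
    Provides two neutral copy-number simulators - a discrete random walk
    along a dated species tree and a multispecies-coalescent stepwise
    mutation model with optional truncation selection - together with
    exact and approximate Wilcoxon rank-sum neutrality tests. Also
    includes a sliding gene-window scan for tissue-specific expression
    clusters, Jensen-Shannon-divergence conservation profiling of protein
    alignments with per-segment nonsynonymous/synonymous summaries, and
    seed-reproducible synthetic-data generators with ground-truth
    sidecars for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    knitr
biocViews: Genetics, Phylogenetics, Coverage, Alignment, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
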