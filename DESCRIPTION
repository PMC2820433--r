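Package: treescope
Title: Annotated Hierarchical Trees: Newick/NHX I/O, Phylogenetic Events
    and Cluster Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A programmable toolkit for hierarchical tree structures built
    around a mutable annotated node type. Reads and writes New Hampshire
    (newick) and New Hampshire eXtended (NHX) formats in several dialects;
    provides iterative traversal, node search, topology editing, pruning,
    distance computations, midpoint and outgroup rooting, and seeded random
    tree generation that scale to trees with hundreds of thousands of nodes.
    A phylogenetic layer infers speciation and duplication events by the
    species-overlap algorithm and by strict gene-tree/species-tree
    reconciliation with gene-loss inference, dates duplications by topology
    scanning, checks monophyly and extracts ortholog and paralog pairs. A
    clustering layer links dendrograms to numeric profile matrices and
    validates partitions with inter/intra-cluster distances, Dunn and
    Silhouette indexes. A rule-driven rendering engine draws trees as ASCII
    art or standalone SVG with user-defined per-node styles and faces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite,
    ape,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
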