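Package: gransucc
Title: Community Succession and Inter-Kingdom Interactions in Granular Biofilms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ecological-inference toolkit for two-kingdom (16S/18S) time series
    from granulating sequencing batch reactors: Hill-number alpha diversity and
    bounded beta dissimilarity between successive samples, phylogenetic-signal
    testing via Mantel correlograms, null models of community assembly (NRI/NTI,
    beta-NTI, Raup-Crick on Bray-Curtis), dual-method (Spearman + SparCC)
    consensus co-occurrence networks with walktrap modules and temporal module
    dynamics, core inter-kingdom bipartite networks, and distance-based
    redundancy analysis with three-way variance partitioning. Includes a
    synthetic two-kingdom reactor-community generator with known ground truth
    (guilds, environmental optima, assembly regimes, inter-kingdom coupling)
    so the whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
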