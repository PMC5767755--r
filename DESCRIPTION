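Package: pancore
Title: Pangenome Partitioning, Orthology Inference and Phylogenetic
    Origin Classification for Microbial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for delineating microbial species
    and genera from whole-genome identity (ANI/AAI), inferring orthologous
    gene families by Markov clustering of an all-against-all protein
    similarity graph, partitioning pangenomes into core, flexible and
    unique strata with sampling-bias-controlled resampling and rarefaction
    model fitting, estimating marker-based genome completeness, and
    classifying the origin of clade-exclusive core gene families (novel,
    low-identity, divergent in-group homolog, or horizontal transfer with
    an inferred donor lineage) from bootstrap neighbor-joining trees.
    Includes a seeded pangenome simulator with planted ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    igraph,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
SystemRequirements: MAFFT (external binary used for multiple sequence
    alignment when building gene-family trees)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
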