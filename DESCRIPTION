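Package: lsgfevo
Title: Evolution of Lineage-Specific Gene Families in Ciliates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for studying the birth, spread and selective regimes of
    lineage-specific gene families (LSGFs) in ciliates and other taxa with
    non-standard genetic codes. Provides ORF calling under alternative genetic
    codes, allelic-variant collapsing, codon-composition screening (GC3s and
    Wright's effective number of codons), gene-family refinement and sharing
    summaries, Dollo-parsimony dating of family births, LCA gene-tree/species-tree
    reconciliation, and group-level codon-model tests of selection intensity
    (RELAX-style K parameter) and episodic diversifying selection (BUSTED-style
    screens) across genome-architecture categories. A synthetic-data module
    simulates species trees, gene-family histories, codon alignments and
    transcriptome-like inputs with recorded ground truth, so every stage of the
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    yaml,
    withr,
    Rcpp,
    stats,
    utils,
    tools,
    phangorn
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
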