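Package: beepiR
Title: piRNA Discovery, Differential Expression, Target Prediction and
    Regulatory Networks from Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for Piwi-interacting RNA (piRNA) analysis
    of small RNA sequencing libraries, modelled on developmental studies of
    the honey-bee (Apis mellifera) larval gut. Collapses reads to tags, maps
    them to a reference genome, sequentially subtracts rRNA/tRNA/snRNA/
    snoRNA/scRNA and miRNA contamination, and calls 24-33 nt uniquely
    mapping candidate piRNAs; normalizes expression to tags per million,
    screens differentially expressed piRNAs with an Audic-Claverie
    pooled-count test (p <= 0.05, |log2 fold change| >= 1); predicts target
    transcripts with a plant-miRNA-style complementarity penalty score and a
    nearest-neighbor RNA duplex free-energy estimate gated at -15 kcal/mol;
    performs Fisher's exact GO/KEGG term enrichment; and assembles bipartite
    piRNA-gene-pathway regulatory networks with SIF and GraphML export. A
    fully parameterized synthetic-study generator with truth tables supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    data.table,
    igraph,
    yaml,
    stats,
    utils,
    methods,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite
Config/testthat/edition: 3
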