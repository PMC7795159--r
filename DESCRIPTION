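Package: tepomics
Title: Integrative Multi-Omics Profiling of Tumor-Educated Platelets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for integrative analysis of
    tumor-educated platelet (TEP) profiles across five molecular layers:
    canonical miRNAs, isomiRs, intron-spanning reads, mRNAs and proteins.
    Provides isomiR classification of small-RNA reads against a mature miRNA
    reference (length variants, non-templated additions, nucleotide variants),
    CPM conversion with a presence filter including a black-and-white rescue
    rule, TMM normalization, differential expression via a negative-binomial
    exact test for count layers and a beta-binomial likelihood-ratio test for
    protein spectral counts, sign-constrained "expected correlation"
    miRNA-gene-protein networks with hub and cross-network core analysis,
    preranked gene-set enrichment with cross-layer term integration, and a
    synthetic multi-omics data generator with planted ground truth for
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    rlang,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
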