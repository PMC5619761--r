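Package: grascensus
Title: Gene-Family Census, Phylogeny, Duplication and Expression Analysis
    for Plant GRAS Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline for genome-wide censuses of the plant
    GRAS transcription-factor family: nomination of family members from
    profile-HMM domain hits with an E-value cutoff, collapsing of splice
    variants to gene loci, per-protein characterization (length, molecular
    weight, isoelectric point), neighbor-joining phylogenies with bootstrap
    support and anchor-based subfamily assignment, paralog detection by
    coverage/identity criteria with tandem/segmental classification,
    exon-intron structure and conserved-motif statistics, expression-matrix
    hierarchical clustering, and comparative-Ct (2^-ddCt) qPCR
    quantification.  A planted-truth synthetic-genome generator makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
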