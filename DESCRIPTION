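Package: acaScan
Title: Genomic Context and Promoter Analysis of Anti-CRISPR-Associated Regulators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterisation of aca-like (anti-CRISPR-associated)
    transcriptional regulators in annotated bacterial genomes. Provides
    position-specific log-odds family profiles and protein scanning, greedy
    redundancy reduction, intergenic-gap operon calling, acr-association
    classification of aca loci (operonic, proximal or solo), strand-aware
    promoter extraction, sigma70 -35/-10 core promoter scanning, mismatch-
    tolerant inverted-repeat detection with IR1/IR2 classification relative to
    the core promoter, Gibbs-sampling motif discovery and motif scanning and
    comparison, gene association networks, family-level statistics with
    Welch tests and neighbor-joining trees, and a synthetic-genome generator
    that plants acr-aca operons, promoters and binding sites with a ground
    truth manifest so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    ape,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
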