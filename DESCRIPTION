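Package: shotgunmb
Title: Shotgun Metabarcoding of Multi-Ingredient Herbal Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Authenticates the plant, fungal and animal ingredients of
    multi-ingredient herbal products from PCR-free shotgun sequencing reads.
    Read pairs carrying one of five standard DNA barcodes (ITS2, psbA-trnH,
    matK, rbcL, COI) are enriched by k-mer comparison against a local
    reference database, assembled with a dual-k de Bruijn mini-assembler,
    trimmed to the inter-primer barcode region (rDNA flank profiles for
    ITS2), clustered into OTUs at 100% identity, validated by mapped depth
    and coverage, and assigned taxa with a top-percent lowest-common-ancestor
    rule; ingredients whose barcodes fail to assemble are recovered by
    organelle-genome read recruitment. Includes a paired-end read simulator
    with truth labels for end-to-end validation on mock mixtures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    S4Vectors,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
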