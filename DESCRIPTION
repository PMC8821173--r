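Package: florin
Title: Integrative ceRNA Network Inference and Case/Control GWAS for
    Late-Flowering Candidate Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for dissecting a late-flowering
    phenotype from multi-omic data: differential expression of mRNAs,
    lncRNAs and miRNAs with FPKM/TPM normalisation and
    Benjamini-Hochberg correction; plant miRNA response element (MRE)
    prediction by position-weighted complementarity scoring; cis/trans
    lncRNA target assignment combining genomic windows, dual
    correlation filters and an additive duplex-energy surrogate;
    hypergeometric shared-MRE testing to assemble
    direction-constrained lncRNA-miRNA-mRNA (ceRNA) triplets; and a
    case/control SNP association scan with Bonferroni thresholding,
    candidate-region extraction and promoter G-box disruption
    annotation. A synthetic-data module generates genotypes,
    annotation, sequences and negative-binomial expression counts with
    planted effects so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
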