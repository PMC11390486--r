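Package: pollenDrive
Title: Simulation and Genomic Mapping of Toxin-Antidote Pollen Gene Drive
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying gametophytic gene drive caused by
    toxin-antidote systems in plant pollen, modelled on the teosinte/maize
    hybrid system in which a hairpin-derived small RNA toxin aborts pollen
    lacking linked and unlinked antidote alleles. Provides an analytic and
    stochastic multi-locus gamete simulator with recombination maps,
    inversion-suppressed recombination and pollination competition;
    single-pollen genotype matrix encoding, consensus imputation, binning and
    drive-interval calling; delta-SNP-index bulked segregant analysis with
    Benjamini-Hochberg control; small RNA cluster calling, size/strand-bias
    classification and hairpin locus identification; small RNA target-site
    scoring with degradome (PARE) support and allele comparison; and
    haplotype-based selection scans (EHH, iHS, Weir-Cockerham FST) in genomic
    windows. Synthetic data generators emulate every input so the full
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    S4Vectors,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
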