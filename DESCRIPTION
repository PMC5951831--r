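Package: deaminoscan
Title: Screening Tumor Cohorts for CpG>TpG Deamination Hypermutation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for discovering tumors whose somatic mutation load
    is dominated by spontaneous deamination of 5-methylcytosine, the
    mutational footprint of MBD4 glycosylase deficiency. Reads somatic
    variant tables (MAF, VCF), merges multi-caller call sets, applies a
    depth/allele-fraction/population-frequency filter cascade, classifies
    single nucleotide variants into the 96 pyrimidine-centered
    trinucleotide channels (SBS96), quantifies the fraction of C>T
    transitions at CpG dinucleotides, screens cohorts for hypermutated
    CpG>TpG-enriched outliers, and characterizes variant sharing between
    primary tumors and metastases. A seeded synthetic-data generator
    produces reference sequences, per-caller call tables and cohorts with
    planted hypermutators, with machine-readable ground truth, so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    vcfR,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
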