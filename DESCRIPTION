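Package: abca1fc
Title: Functional Characterization and ACMG/AMP Classification of ABCA1 Missense Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for fluorescence-based cholesterol efflux assays of
    ABCA1 missense variants and their clinical interpretation. Computes relative
    cholesterol efflux from plate-reader signals with background and mock-transfection
    corrections, assigns functional categories against wild-type-normalized thresholds,
    quantifies cell-surface ABCA1 from densitometry with total-protein correction,
    evaluates chemical-chaperone (4-PBA) rescue, maps variants onto ABCA1 domains and
    ATP-binding motifs, aligns the two nucleotide-binding domains to propose equivalent
    variants, and combines ACMG/AMP evidence (including gene-calibrated allele-frequency,
    phenotype, and functional-assay criteria) into the five-tier pathogenicity class.
    Includes a synthetic-data generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
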