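Package: cnvphen
Title: Phenotype Descriptions for Chromosome Deletions from Genotypically
    Similar Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates tailored phenotype descriptions for patients carrying
    chromosome deletions (or duplications) by pooling the coded phenotypes of
    genotypically similar patients in a cohort. Genes are classified as
    haploinsufficient (HI) from HI percentile, pLI and pHaplo scores; patient
    pairs are compared by Jaccard overlap of deletion size, location, gene and
    HI-gene content, gated on concordance of dominating-effect genes; a tiered
    algorithm picks the highest HI-gene similarity threshold that still yields
    a sufficiently large group, and features prevalent in that group form the
    description. Includes the positive-predictive-value (PPV) leave-one-out
    evaluation machinery used to calibrate the similarity thresholds, a
    synthetic-cohort simulator for end-to-end testing, and tab-separated
    readers/writers plus a small command-line interface.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
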