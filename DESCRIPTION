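Package: famreml
Title: Partitioning Phenotypic Variance into SNP, Pedigree and
    Shared-Environment Components
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Variance-component analysis for family-structured cohorts.
    Builds genomic relationship matrices (GRM) from SNP dosages, a
    thresholded GRM capturing pedigree-associated genetic sharing, and
    0/1 environmental relationship matrices for couples, full siblings
    and nuclear families; fits any combination of these components by
    average-information REML; performs Wald and boundary-corrected
    likelihood-ratio tests with backward stepwise model selection; and
    validates the whole pipeline by parameter recovery on a gene-drop
    simulator of nuclear-family cohorts.  Includes PLINK binary and GCTA
    GRM file support, quality-control filters and a relatedness-cutoff
    scan of heritability estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
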