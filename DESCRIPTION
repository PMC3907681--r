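Package: famgreml
Title: GREML Variance Decomposition for Family Socioeconomic Environment and
    Child Cognitive Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: DNA-based quantitative-genetic analysis of family-level
    environmental measures (such as family socioeconomic status) and child
    cognitive phenotypes in samples of unrelated individuals.  Implements
    genetic relatedness matrix (GRM) construction from SNP genotypes,
    genotype quality control and relatedness pruning, ancestry principal
    components with Tracy-Widom axis selection, phenotype composites with
    rank-based inverse-normal transformation, univariate and bivariate
    average-information REML (GREML) variance decomposition with the
    boundary likelihood-ratio test, derived genetic and residual
    correlations with delta-method standard errors, and the percentage of a
    phenotypic correlation mediated genetically.  A family-structured
    genotype and phenotype simulator with Mendelian transmission and known
    truth makes every stage testable without restricted cohort data.
    Reads and writes PLINK 1 bed/bim/fam and GCTA binary GRM triplets.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
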