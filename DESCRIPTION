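Package: kinherit
Title: Heritability and Mixed-Model Association in Family Studies with
    Pedigree and Empirical Kinships
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Variance-components estimation of narrow-sense heritability for
    quantitative traits measured in extended pedigrees, using either the
    expected kinship matrix computed from genealogy or an empirical genetic
    relationship matrix (GRM) estimated from genome-wide SNP dosages.
    Includes pedigree file parsing and validation, genotype QC
    (Hardy-Weinberg filtering, windowed LD pruning), method-of-moments IBD
    relationship inference with pedigree discordance screening, covariate
    residualization with founder-based principal components and rank-based
    inverse-normal transformation, single-variant mixed-model association
    (measured genotype analysis), and a gene-dropping simulator that
    generates pedigrees, genotypes and traits with specified heritability
    for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite
Config/testthat/edition: 3
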