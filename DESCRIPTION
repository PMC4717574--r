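Package: AssortMate
Title: Genetic Basis of Height-Mediated Mate Choice via GREML on Synthetic Couple Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the genetic contribution to mate-height choice with
    genomic-relationship-matrix restricted maximum likelihood (GREML).
    Provides a synthetic cohort generator for phenotype-driven assortative
    mating (couples whose heights correlate through noisy rank matching),
    genotype and phenotype quality control, genomic relationship matrices and
    principal components, univariate and bivariate average-information REML
    with BLUP of additive effects and SNP effects, partner-height polygenic
    prediction, a couple-swap permutation control that preserves height
    assortment while destroying within-couple genetic and environmental
    structure, and closed-form assortative-mating theory (expected mate-choice
    heritability, random-mating heritability, heritability inflation,
    breeding-value correlation among mates).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
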