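Package: caninegp
Title: Pedigree and Genomic Prediction of Canine Hip Dysplasia Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for comparing pedigree-based and
    genomic prediction of hip-score traits in dog populations. Provides a
    synthetic-cohort generator (pedigree simulation, gene dropping, hip-score
    phenotypes), marker quality control for PLINK PED/MAP panels, pedigree
    (A), genomic (VanRaden) and single-step (H-inverse) relationship matrices,
    animal-model REML heritability estimation by eigendecomposition, four
    breeding-value predictors (BLUP, GBLUP, Bayes C via a Gibbs sampler, and
    single-step BLUP), and a k-fold cross-validation harness with
    predictive-ability statistics, single-marker GWAS ranking and
    marker-density experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    splines,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
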