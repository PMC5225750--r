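Package: clonalGS
Title: Genomic Selection for Clonally Replicated Breeding Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end genomic selection analysis for clonally replicated
    field trials, as used in strawberry and other asexually propagated
    crops. Provides marker quality control and mean imputation, pedigree
    and marker-based (Yang et al.) relationship matrices with eigenvalue
    bending, an average-information REML engine for the clonal trial mixed
    models (narrow- and broad-sense heritability, Type-B genotype-by-trial
    correlation, generalized-least-squares adjusted clonal means), Gibbs
    samplers for whole-genome regression (Bayesian ridge, Bayesian LASSO,
    Bayes B, Bayes C), kernel-based prediction (GBLUP, PBLUP, Gaussian-kernel
    RKHS), cross- and true-validation with predictive ability, prediction
    accuracy and selection efficiency, relatedness-corrected linkage
    disequilibrium, and a breeding-population simulator (circular mating,
    gene dropping with Haldane recombination) so every stage can be tested
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
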