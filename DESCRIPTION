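Package: alderia
Title: Quantitative Genetics of Developmental-Mode Plasticity in a
    Poecilogonous Sea Slug
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Threshold-trait (liability) quantitative genetics for
    poecilogonous species whose clutches develop either
    planktotrophically or lecithotrophically.  Provides Bayesian animal
    models (Gaussian, binary probit, and categorical responses) fitted by
    Gibbs sampling with data augmentation over pedigree-derived additive
    relationship matrices that accommodate self-fertilization; conversion
    of variance components between the latent liability scale and the
    observed data scale; realized heritability from truncation-selection
    experiments via the probit-transformed breeder's equation; family
    reaction norms and cross-environment genetic correlations; and a
    forward simulator of split-brood, multi-generation
    selection-with-selfing designs for validating the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
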