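Package: stillbirthSMGS
Title: Sire-Maternal-Grandsire Threshold-Model Genetic Evaluation of Stillbirth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-breed genetic evaluation of stillbirth in dairy cattle
    with a Bayesian sire-maternal-grandsire (S-MGS) threshold model.
    Provides editing rules for national calving records, construction of the
    pedigree relationship-matrix inverse under sire-MGS rules, Gibbs sampling
    with truncated-normal data augmentation for liability-scale variance
    components, transformation of sire/MGS (co)variances to direct and
    maternal genetic parameters with highest-posterior-density summaries,
    observed-scale predicted transmitting abilities (service-sire and
    daughter stillbirth percentages) anchored to birth-year genetic bases,
    approximate reliabilities from mixed-model-equation diagonals, and
    phenotypic/genetic trend estimation. A generative simulator reproducing
    the model's liability structure supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    coda
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
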