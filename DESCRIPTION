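Package: ipvgsem
Title: Latent-Factor Generalized SEM and Survey-Weighted Analysis of
    Intimate Partner Violence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing intimate partner violence (IPV) in
    DHS-style complex survey data. Derives binary physical, emotional and
    sexual IPV outcomes and composite covariates from item-level
    responses; computes design-weighted prevalence estimates with
    cluster-robust (Taylor linearization) confidence intervals; pools
    country prevalences by DerSimonian-Laird random-effects meta-analysis
    with heterogeneity statistics; and fits a generalized structural
    equation model in which a latent husband-controlling-behaviour factor,
    measured by binary indicator items, jointly predicts the three IPV
    domains through logit links. Estimation is by weighted (pseudo-)
    marginal maximum likelihood with Gauss-Hermite quadrature, with
    sandwich variance estimation clustered on primary sampling units.
    Includes a two-stage cluster-sampling simulator that generates
    synthetic woman-level survey data with known parameters for testing
    and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    pracma,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
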