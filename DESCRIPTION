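Package: lstitem
Title: Longitudinal Multi-State Measurement Models with Person-Specific
    Item-Effect Variables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits longitudinal multi-state measurement models for short
    rating scales, with and without person-specific item-effect variables in
    the tradition of revised latent state-trait (LST-R) theory.  Provides
    normal-theory maximum likelihood and full-information maximum likelihood
    estimation of the moment structure, model fit indices (chi-square, RMSEA
    with 90% confidence interval, SRMR, CFI, TLI, AIC, BIC), extraction of
    latent means, standard deviations and correlations with Wald-type
    significance flags, the exact linear reparameterization between reference
    items, structural regressions of outcome composites on the latent state
    and item-effect variables with standardized coefficients and incremental
    variance explained, and a synthetic panel-data generator emulating a
    five-item, three-wave satisfaction-with-life design with wave-level unit
    nonresponse.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
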