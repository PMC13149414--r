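Package: sharedmap
Title: Shared-Component Bayesian Spatio-Temporal Disease Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint Bayesian spatio-temporal modelling of multi-disease
    mortality panels at areal (country) resolution. Observed death counts are
    modelled as Poisson around expected deaths derived from age-standardized
    rates, with log relative risk decomposed into disease intercepts, fixed
    covariate effects, shared and disease-specific BYM2 spatial effects,
    shared and disease-specific first-order random-walk temporal effects, and
    an iid space-time interaction grouped by disease. Hyperparameters carry
    penalized-complexity priors. Inference combines a Newton-Laplace
    approximation of the latent Gaussian field with adaptive random-walk
    Metropolis over hyperparameters. Includes expected-death standardization,
    covariate screening (VIF), posterior diagnostics (DIC, WAIC, CPO/LCPO,
    PIT, observed-vs-fitted), effect-surface extraction, and a seeded
    synthetic-panel generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
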