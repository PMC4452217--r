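Package: possumOccAb
Title: Joint Occupancy-Abundance Modelling and Survey-Design Evaluation
    for Large-Scale Possum Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for grid-based monitoring of invasive brushtail possums
    from paired leg-hold trap-line and faecal-pellet transect surveys.
    Implements the Trap Catch Index (TCI) protocol with 0.5 trap-night
    corrections, a joint Bayesian site-occupancy / zero-inflated abundance
    model with imperfect per-line detection fitted by a Gibbs-within-
    Metropolis sampler, evaluation of reduced survey effort (fewer trap
    nights and trap-lines) by repeated without-replacement subsampling,
    two-sample t-test power calculations for detecting changes in mean
    TCI, and a fixed/variable cost model for the annual monitoring
    programme. A synthetic-data generator reproduces the statistical
    structure of the national 8-km-grid survey design so every stage can
    be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    coda
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'tci.R'
    'core_data.R'
    'cost.R'
    'diagnostics.R'
    'likelihood.R'
    'fit.R'
    'effort.R'
    'oracle.R'
    'utils.R'
    'power.R'
    'synthetic.R'
    'pipeline.R'
    'possumOccAb-package.R'
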