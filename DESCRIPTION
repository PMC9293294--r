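Package: n2oef
Title: Disaggregated Emission Factors and Tier 1 Monte Carlo Inventories for
    Direct Soil N2O Emissions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for refining the IPCC Tier 1 EF1 emission factor for direct
    soil nitrous oxide emissions from nitrogen inputs to managed soils.
    Computes control-plot emission factors from field experiments, applies the
    standard study inclusion filters, classifies observations by climate,
    fertilizer form, nitrogen rate, land cover and topsoil properties, and
    fits per-factor linear mixed models with a location random intercept,
    LSD Fisher mean separation and class-merging support. A Monte Carlo
    inventory engine propagates triangular emission-factor uncertainty over
    gridded cropland nitrogen inputs, aggregates emissions to country and
    global scope with quantile confidence intervals, and compares the 2006
    IPCC Guidelines scheme against the 2019 Methods Refinement scheme.
    Synthetic data generators emulate both the emission-factor dataset and
    the fertilizer-nitrogen grid so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
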