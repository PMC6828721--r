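Package: aquarisk
Title: Probabilistic Health-Risk Assessment of Heavy Metals in Groundwater
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exposure-dose and risk equations (chronic daily intake, hazard
    quotients, lifetime cancer risk), seeded Monte Carlo propagation of
    concentration and exposure-factor distributions with percentile and
    exceedance reporting, rank-correlation sensitivity shares, correlation and
    principal-factor source apportionment, and inverse-distance-weighted
    spatial interpolation for multi-district groundwater quality studies.
    Includes a synthetic-data generator that reproduces a two-district,
    two-source (borehole and hand-dug well) sampling design from published
    summary statistics, so the full pipeline runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
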