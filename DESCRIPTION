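Package: ngtp
Title: Climate Accounting of Nitrogen Use in Agriculture via Global
    Temperature Change Potential
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annual nitrogen budgets for global agriculture built from five
    input sources (synthetic fertilizer, animal manure, crop residue,
    atmospheric deposition, biological nitrogen fixation), converted to gas
    fluxes (direct and leaching-indirect N2O, NO3 leaching, NH3, NOx, CH4,
    CO2 sequestration) with Tier-1 style emission and uptake factors, and
    mapped to CO2-equivalent warming and cooling at 20- and 100-year horizons
    with the Global Temperature change Potential (GTP) metric. Provides an
    explicit warming/cooling decomposition, net GTP, low/mid/high coefficient
    envelopes, period aggregation over multi-year series, and a seeded
    generator of FAOSTAT-like annual series anchored at published 1961 and
    2010 records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
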