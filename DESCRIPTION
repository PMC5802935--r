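Package: metaflux
Title: Meta-Ecosystem Flux Networks and Ecological Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning a heterogeneous landscape's ecosystem flux
    budget into a (quasi-)closed meta-ecosystem flow network and analysing it
    with Ecological Network Analysis (ENA). Implements a four-step protocol:
    encode compartment-to-compartment flux records as a validated flow
    network; flag flux significance against per-ecosystem throughput and
    classify the landscape system (systemic, fragmental, or discrete); adjust
    a fragmental system to a closed meta-ecosystem by introducing exterior
    compartments and resolving accumulation sign conventions; and compute the
    holistic flow-network indices (total system throughput, average mutual
    information, ascendency, development capacity, redundancy) together with
    spatial flux budgets built from areal and lineal flux intensities. Ships
    the Northern Highlands Lake District (NHLD) carbon-budget example, a
    seeded synthetic-network generator for property testing, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
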