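Package: bioisru
Title: Process Model for Biological In Situ Production of 2,3-Butanediol Rocket Propellant on Mars
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Techno-economic process model of a biotechnology-enabled in situ
    resource utilization (bio-ISRU) strategy that produces 2,3-butanediol rocket
    propellant on Mars from carbon dioxide, sunlight and water. Includes
    combustion thermochemistry and theoretical specific-impulse calculations for
    oxygenated fuels, ideal-rocket-equation mission sizing, a light-limited
    cyanobacterial growth model for suspended and biofilm cultivation, unit
    operation sizing with water/power/payload accounting (cross-flow
    concentration, enzymatic digestion, continuous fermentation), a converged
    liquid-liquid extraction / pervaporation / water-recycle separation train
    with an NRTL activity model, mission-level mass and oxygen balances with
    materials substitution scenarios, and a constraint-based (flux balance
    analysis) theoretical-yield calculator for short-chain diol pathways.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
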