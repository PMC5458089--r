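Package: terpflux
Title: Kinetic Modelling of Cell-Free Glucose-to-Monoterpene Biosynthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic kinetic model of a cell-free enzymatic system that
    converts glucose into monoterpenes (limonene, pinene or sabinene) through
    glycolysis, a nicotinamide-cofactor purge valve and the mevalonate pathway,
    with full in-situ recycling of ATP, NAD(H), NADP(H), coenzyme A and
    phosphate. Provides the reaction network as editable data, a rate-law
    library, a stiff ODE simulator with conserved-moiety auditing, parameter
    scans, bottleneck identification and purge-valve knockout experiments,
    stoichiometric net-conversion and yield/productivity analysis, and a
    generator of noisy triplicate assay datasets for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    MASS,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
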