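Package: svatdrought
Title: Forest Water Balance Simulation and Physiological Drought Indices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Soil-vegetation-atmosphere-transport (SVAT) water-balance
    modelling for forest drought analysis. Provides pedotransfer-based
    Mualem-van Genuchten soil hydraulic parameterization with
    plant-available water capacity and uncertainty propagation, a daily
    Brook90-style one-dimensional water-balance simulator (Rutter
    interception, degree-day snow, Shuttleworth-Wallace two-source
    potential evapotranspiration, supply-limited root water uptake, and
    an implicit Richards-equation soil water solver), GLUE-style
    Monte-Carlo-filtering calibration against depth-resolved soil matric
    potential with Kolmogorov-Smirnov sensitivity screening, and
    physiological drought indices (transpiration deficit, Ta/Tp,
    available-water deficit, relative available water, rooting-zone
    matric potential). A synthetic-site generator supplies meteorology,
    soil profiles, and truncated-range virtual sensor records with known
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    zoo
Config/testthat/edition: 3
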