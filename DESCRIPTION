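Package: ednadvm
Title: Vertical Distribution of Environmental DNA Shed by Diel Vertical Migrators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A one-dimensional mechanistic model of the fate and transport of
    environmental DNA (eDNA) shed by mesopelagic organisms that perform diel
    vertical migration. Two eDNA size classes (settling large particles and
    neutrally buoyant small particles) are advected, mixed, decayed, and
    broken down in a vertical water column while a migrating cohort releases
    eDNA along its daily trajectory. Includes seasonal synthetic forcing
    profiles, NOAA solar-position migration timing, analytic transport length
    scales, depth-bin profile metrics, a factorial sensitivity sweep, and
    inversion of the percentage of migrating individuals from surface-to-deep
    concentration ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
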