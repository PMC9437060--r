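Package: medusadrift
Title: Lagrangian Connectivity and Stranding Analysis for an Idealized Tidal Strait
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Biophysical transport toolkit for studying larval connectivity
    between a spawning basin and a tidal strait. Generates idealized gridded
    current and wind forcing (semi-diurnal tidal jet over a sill, residual
    through-flow with an anticyclonic recirculation cell, weak basin drift
    around island obstacles), advects passive surface drifters with windage
    and random-walk diffusion, classifies stranding, gate exits and domain
    loss against a planar coastline geometry, and computes connectivity
    metrics: the Normalized Source Index, travel-time maps, strait entry
    ratios, occupancy and retention series and per-segment stranding shares.
    Companion routines implement beach-survey analytics for stranded
    jellyfish (allometric biomass, size-class and abundance-class tables)
    and habitat statistics (current-speed distributions, upwelling depth
    from a density-anomaly threshold).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
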