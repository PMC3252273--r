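Package: antroute
Title: Familiarity-Based Simulation of Visual Route Navigation in Ants
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of visually guided route navigation in
    desert ants. Generates procedural tussock-grassland worlds from flat
    black triangular patches, renders low-resolution (90 x 17) panoramic
    skyline views by spherical projection and block-average down-sampling,
    scaffolds training routes with path integration modulated by skyline
    obstacle avoidance, and recapitulates routes with a scanning agent that
    moves in the direction whose view is most familiar. Familiarity is
    scored either by exhaustive comparison with stored views (perfect
    memory, rotational image differences) or by a single-pass Infomax
    novelty network trained with the natural gradient of mutual
    information. Includes scripted experiments (experience curves,
    learning-walk nest search, multiple-route retention), familiarity and
    heading grid maps, and plain-text world and path interchange formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
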