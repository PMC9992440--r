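Package: sargdrift
Title: Backtracking and Morphotype Composition Analysis of Pelagic Sargassum Strandings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to link the seasonal morphotype composition of stranded
    pelagic Sargassum (S. natans I, S. natans VIII, S. fluitans III) to
    oceanic sub-origins and transport pathways. Provides a year-day surface
    current climatology built from drifter fixes, backward and forward
    Lagrangian particle tracking with windage and a stochastic turbulence
    model, K-means partitioning of trajectory metrics into sub-origin
    pathways, compositional data analysis of three-part morphotype volumes
    (isometric log-ratio transform, ternary coordinates), PERMANOVA with a
    restricted nested permutation scheme, a multivariate dispersion
    homogeneity test, and environmental (sea surface temperature and
    chlorophyll-a) contrasts between pathways. A synthetic data module
    generates current, wind and environmental fields with a planted
    two-pathway seasonal structure so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    graphics,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
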