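Package: reefscape
Title: Intra-Reef Landscape Genetics for Clonal Corals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based landscape genetics within a single coral patch
    reef. Computes depth-independent thermal indices (Relative Hotspots and
    Relative Hothours) from temperature-logger grids, interpolates depth and
    the indices onto colony locations by ordinary kriging, estimates pairwise
    Moran's-I coefficients of relationship from microsatellite genotypes, and
    links relatedness to depth, space and temperature with simple and partial
    Mantel permutation tests, AIC multi-model inference with Akaike and
    predictor weights, distance-binned autocorrelograms, spatial principal
    component analysis over neighbour networks with Moran's eigenvector map
    randomization tests, and pairwise AMOVA F(ST) between size classes after
    clone deduplication. Includes a synthetic-reef generator with tunable
    depth cline, isolation by distance and clonality for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS
Config/testthat/edition: 3
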