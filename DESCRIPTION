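Package: morphorep
Title: Repeatability, Reproducibility and Separative Power of Fish
    Morphometric Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies and compares the repeatability (intra-measurer
    similarity), reproducibility (inter-measurer similarity), separative
    power and measurer subjectivity of landmark-based geometric
    morphometrics (body and scale landmarks) and distance-based
    morphometrics (truss-network and caliper measurements) for fish
    population studies.  Provides generalized Procrustes superimposition
    with tangent projection and shape-on-size regression, Elliott
    allometric size standardization of linear measurements, pairwise
    Mantel tests on Euclidean distance matrices arranged into
    hierarchical measurer/species/method comparisons with Kruskal-Wallis
    letter displays, canonical variate analysis with permutation-based
    population detachment, two-way permutational multivariate analysis of
    variance (PERMANOVA) on crossed site-by-measurer designs, a synthetic
    data generator emulating a fully crossed
    species-by-site-by-individual-by-measurer-by-repeat measurement
    design, and a pipeline driver with TPS and CSV input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
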