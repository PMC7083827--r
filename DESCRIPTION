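Package: centrale
Title: Geometric-Morphometric Test of Centrale Fusion Versus Loss in the
    Archosauromorph Tarsus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether the archosaur astragalus incorporates the
    centrale (fusion) or whether the centrale was lost as an independent
    ossification. Implements reading and writing of 2D landmark data in TPS
    format, generalized Procrustes analysis with Procrustes-distance sliding
    of semilandmarks, principal component morphospaces with Sum-of-Variances
    disparity, minimum-distance superimposition onto a reference taxon,
    parsimony reconstruction of ancestral landmark configurations on fixed
    phylogenies (minimum total Euclidean landmark displacement, solved per
    landmark as a convex multifacility Weber problem), branch-specific
    landmark-displacement comparison between alternative landmark
    configurations, and a synthetic-data generator (Brownian shape evolution
    on a tree with a controllable focal-branch medial displacement) for
    calibrating the decision rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
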