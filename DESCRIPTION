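Package: covgrad
Title: Structural Covariance, Twin Genetics, and Macroscale Cortical Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the macroscale organization of parcellated
    cortical phenotypes. Builds structural-covariance networks from
    covariate-residualized cortical thickness, decomposes inter-regional
    correlations into additive-genetic and unique-environmental components
    with twin-based AE maximum-likelihood models, extracts macroscale
    gradients by normalized-angle affinity and diffusion-map embedding, and
    provides spatially aware inference: spherical spin permutation tests,
    energy two-sample tests, geodesic distances from archi- and paleocortical
    origins, and microstructural profile covariance from equivolumetric depth
    sampling. Includes a synthetic twin-cohort generator with planted
    genetic/environmental gradient structure so every stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
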