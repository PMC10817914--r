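Package: wmconstraint
Title: White-Matter Connectome Constraints on Cortical Thickness Maturation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for testing how the architecture of the white-matter
    structural connectome shapes the maturation of cortical thickness from
    childhood to adolescence. Provides synthetic generators for spherical
    parcellations, distance-dependent binary connectomes and longitudinal
    cortical-thickness rosters; distance-binned consensus backbones and nodal
    graph metrics; three maturation models (mixed-effects group contrast,
    penalized-spline age trajectories, individual annualized change);
    neighbor-constraint correlations with spin and degree-preserving rewired
    null models; a multiscale random-walk diffusion model with cross-validated
    support-vector-regression prediction; dominant-node identification by
    cosine similarity and rank-based methods; and dominant versus non-dominant
    gene-expression contrasts with gene-resampling nulls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    deldir,
    lme4,
    lmerTest,
    mgcv,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
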