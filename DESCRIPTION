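Package: lymphwalk
Title: Quantitative Analysis of T-Cell Motility and Search Efficiency in Lymph Nodes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical characterization of naive T-cell motility from 3D
    cell tracks: angle-threshold step segmentation, maximum-likelihood
    model competition between lognormal, Gaussian, Maxwell, exponential,
    gamma and power-law step-length and speed distributions, Clauset-style
    power-law tail estimation, mean-squared-displacement anomalous-diffusion
    exponents and motility coefficients, velocity auto- and
    cross-correlation, a continuous 3D agent-based search-efficiency
    simulator comparing six random-walk models against clustered targets
    (with a 3D Hopkins aggregation statistic), a simulation-null-model
    hotspot detector on a 20 um grid, sliding-window heterogeneity
    statistics, and seeded synthetic track generators with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
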