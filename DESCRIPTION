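Package: voxdevo
Title: Evolution and Ballistic Development of Soft Voxel Robots
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An in-silico evo-devo laboratory for soft voxel robots.
    Robot morphologies (per-voxel resting lengths) and controllers
    (per-voxel actuation phase offsets) develop linearly over a lifetime
    ("ballistic" development) while the robot locomotes in a mass-spring
    voxel physics simulation, and are optimized by Age-Fitness-Pareto
    evolution with self-adaptive per-voxel mutation rates. Includes an
    analysis battery for studying differential canalization: developmental
    window statistics, lineage tracing of run champions, mutation-robustness
    random walks, rollover-onset heterochrony measurements, a
    development-removal experiment, and rank-based hypothesis tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tibble,
    rlang,
    stats,
    utils,
    tools,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
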