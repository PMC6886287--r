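Package: autofmo
Title: Automatic Importance-Factor Optimization for IMRT Inverse Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fluence-map optimization (FMO) for intensity-modulated radiation
    therapy with prescription-value-based automatic tuning of the importance
    factors that weight the planning objective. Provides synthetic 2-D planning
    phantoms with beamlet-resolved dose-influence matrices, three objective
    models (dose-volume, gEUD, and LKB-NTCP based), an L-BFGS inner solver on
    square-root beamlet weights, plan-quality metrics (DVH, conformity and
    homogeneity indices, gEUD, NTCP), and the outer weight-adjustment,
    plan-evaluation, and compensation loops that drive a plan to the
    prescribed acceptability criteria without manual weight tweaking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
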