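Package: seedtherm
Title: Crystal Solubility and Nucleation Thermodynamics from Finite-Size
    Seeded Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates polymorph-specific solubility and effective surface
    energy of molecular crystals from the steady-state sizes of crystalline
    seeds observed in finite, thermostated molecular-dynamics simulations.
    In a closed simulation box the growth of a nucleus depletes the
    surrounding solution, which turns the classical nucleation free-energy
    profile into one with a stable minimum; locating that minimum for
    several box compositions and solving the resulting stationarity
    conditions as a nonlinear least-squares problem yields
    simulation-independent thermodynamic parameters. The package extends
    these to Van't Hoff solubility curves, dissolution enthalpies,
    classical nucleation barriers, metastable-zone limits, stability maps
    in the composition/volume plane, and relative polymorph stability, and
    ships an orientation-fingerprint classifier to extract largest-cluster
    time series from trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
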