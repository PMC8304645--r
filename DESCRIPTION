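Package: ifacedyn
Title: Interface Stability Analysis of Protein Complexes from Simulated Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to quantify the stability of a protein-protein interface
    from molecular simulation output: interface atom-pair counts and buried
    surface areas decomposed by binding-partner domain, residue-level contact
    maps from a C-alpha distance rule applied across trajectory frames,
    mean-square fluctuation of inter-residue distances (MSFD) with region
    averaging, exclusion and condition-comparison rules, and
    potential-of-mean-force estimation from steered-pulling work records via
    Jarzynski's equality with a second-cumulant approximation. A synthetic-data
    module generates two-chain complexes, fluctuating trajectories and Brownian
    pulling ensembles with closed-form ground truth, so the whole pipeline is
    testable without running molecular dynamics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
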