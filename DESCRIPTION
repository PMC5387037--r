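Package: mesoflux
Title: Mesophyll Resistance Models of C3 Leaf Gas Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward simulation and estimation tools for C3 leaf
    photosynthesis with a two-component mesophyll resistance network.
    Couples Farquhar-von Caemmerer-Berry (FvCB) biochemistry to cell-wall/
    plasmalemma and chloroplast diffusion resistances, with organelle
    arrangement parameters controlling how (photo)respired CO2 re-enters
    the network. Computes A-Ci curves, apparent and intrinsic mesophyll
    conductance, CO2 compensation points and the fraction of (photo)respired
    CO2 refixed by Rubisco; reproduces the variable-J estimation artifact;
    and fits intrinsic mesophyll conductance together with the effective
    chloroplast-resistance sensitivity from multi-O2 gas exchange data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
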