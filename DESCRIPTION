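Package: swimmaze
Title: Swim-Path Strategy Analysis for the Morris Water Maze
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation, classification and statistical analysis of swim-path
    strategies in the Morris water maze. Generates labelled synthetic swim
    trajectories for six exploratory strategy classes (thigmotaxis, scanning,
    circling, focal search, rotating, direct swim), extracts scale-free
    geometric features and classifies paths by explicit rules, rasterizes
    trajectories to grayscale images, trains a small two-convolution-layer
    neural network for 2-, 3- and 6-class path recognition, and reproduces
    stage frequency tables, presence-of-strategy outcome comparisons and
    cognitive-score transition analyses on simulated cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
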