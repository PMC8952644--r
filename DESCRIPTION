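Package: fretsphere
Title: Energy Transfer and Migration on Dye-Labelled Core-Shell Nanoparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative modelling of Foerster resonance energy transfer (FRET)
    for fluorophores bound to the surface of spherical core-shell nanoparticles.
    Provides the analytical single-step donor fluorescence decay with a
    truncated-Gaussian particle-size distribution, a Gillespie kinetic
    Monte-Carlo engine for multistep donor-donor energy migration and trapping
    on particle realizations, a synthetic time-correlated single-photon counting
    (TCSPC) generator with Poisson noise and optional Gaussian instrument
    response, and least-squares fitting to recover acceptor numbers and
    size-distribution parameters from decay curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    rlang,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
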