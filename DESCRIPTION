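Package: admixmate
Title: Ancestry-Assortative Mating Simulation and Inference from Local-Ancestry Tract Lengths
Version: 0.1.0
Authors@R:
    person("admixmate", "developers", email = "admixmate@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of three-way admixed populations under a
    mechanistic mating model in which ancestry-assortative mating (AM) and
    ancestry-related sex bias (SB) shape couple formation, with optional
    two-pulse migration (gene flow rate, GFR). Tracks local-ancestry tracts on
    22 autosomes and the X chromosome, summarises genomes as log-binned
    continuous ancestry tract-length profiles, and infers mating parameters by
    simulation-based inference with an ensemble of branched fully-connected
    neural networks. Includes composite-likelihood model comparison between
    one-pulse and two-pulse migration histories, readers and writers for
    window-grid local-ancestry calls and ancestry-segment tables, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
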