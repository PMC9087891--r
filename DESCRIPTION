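Package: msciTowers
Title: Unidentifiable Towers and Relabeling Algorithms for
    Bidirectional-Introgression Multispecies Coalescent Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for working with multispecies-coalescent-with-introgression
    (MSci) models that contain bidirectional introgression (BDI) events. A BDI
    event between two populations creates label-switching unidentifiability:
    with m BDI events between sister lineages and n between nonsister lineages
    the posterior contains 2^n unidentifiable models, each with 2^m
    within-model towers. The package parses and validates MSci model
    descriptions, detects and classifies BDI events, enumerates the
    unidentifiable towers together with their exact parameter mappings
    (complementing introgression probabilities and swapping the parental
    population sizes), and removes label switching from MCMC sample tables
    with three relabeling algorithms: the center-of-gravity algorithms CoG0
    and CoGN and the beta-gamma maximum-likelihood algorithm. It also
    summarizes posterior samples (means, highest-posterior-density intervals,
    effective sample sizes), simulates gene trees under MSci models by the
    backwards-in-time coalescent with episodic introgression, generates
    synthetic label-switching sample tables with known tower labels, and
    computes ABBA-BABA site-pattern statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    fitdistrplus,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
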