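Package: popcoding
Title: Population-Coding Analysis of Hippocampal Spike Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for population coding in head-fixed virtual-reality
    hippocampal recordings: Skaggs spatial information with circular-shuffle nulls,
    z-scored firing-rate correlation matrices and thresholded functional graphs,
    Shannon entropy of 10 ms binary activity patterns, pairwise maximum-entropy
    (Ising) models fitted by exact enumeration with Kullback-Leibler divergence and
    coactivity-resolved prediction-error decomposition, sharp-wave/ripple detection
    and peri-event modulation statistics, a k-nearest-neighbour decoder over the
    (correlation, entropy, KLD) coding space, and a bootstrap variance-ratio test.
    A seeded synthetic-session generator (place fields, Ising-coupled rasters,
    ripple-bearing LFP) provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
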