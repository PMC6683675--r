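Package: tastespike
Title: Analysis of Taste-Evoked Spike Trains in Freely Licking Rodents
Version: 0.1.0
Authors@R:
    person("Morgan", "Avery", email = "morgan.avery@example.org",
           role = c("aut", "cre"))
Description: Tools for single-unit electrophysiology recorded in freely
    licking rodents during brief-access taste testing. Implements sliding
    window detection of taste-evoked responses at the five-lick and
    lick-by-lick time scales, spike-lick spectral coherence with peak
    extraction in the licking band, lick-relation cell classification,
    licking microstructure metrics, and metric-space (Victor-Purpura)
    temporal-coding analysis with shuffle and exchange controls. A seeded
    synthetic session generator with lean and diet-induced-obese presets
    provides ground truth for every stage, so the full pipeline runs with
    no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
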