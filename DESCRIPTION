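Package: mupool
Title: Motor-Unit-Resolved Simulation of Isometric Muscle Force from
    Motoneuron Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the isometric force produced by a complete pool of
    motor units driven by motoneuron spike trains. Builds muscle-specific
    motor-unit pools (recruitment-threshold, twitch-force, tetanic-force and
    innervation-ratio distributions with a slow/fast fibre-type partition),
    maps experimentally identified motor units into the pool and assigns
    them representative forces, transforms each spike train into an active
    state through cascaded excitation-contraction coupling differential
    equations (motoneuron and fibre action potentials, free calcium,
    calcium-troponin binding, active state), scales force with an
    activation-dependent force-length relationship, and assembles per-unit
    and whole-muscle forces. Also estimates the effective neural drive from
    cumulative spike trains and computes the validation metrics used to
    compare predicted and reference force traces. A seeded synthetic
    spike-train generator emulating trapezoidal isometric tasks with
    onion-skin rate coding makes the whole pipeline testable without
    experimental recordings.
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
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
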