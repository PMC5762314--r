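Package: cscsim
Title: Empirical-Sampling Simulation of Cancer Stem-Like Cell Population Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time, multi-type stochastic simulation of mixed cancer
    cell populations (ALDH+ stem-like and ALDH- bulk compartments) driven by
    empirical offspring histograms estimated from single-cell microfluidic
    chamber observations. Provides estimation of per-type offspring
    distributions, quiescence fractions and division statistics from chamber
    tables; a seeded multi-type branching simulator with ensemble median
    summaries and a deterministic mean-field oracle; a synthetic chamber-data
    generator with presets calibrated to published summary statistics; scenario
    presets for in-vitro and in-vivo experiments including tumor-volume to
    cell-count conversion; and prediction-versus-observation comparison by
    Pearson correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
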