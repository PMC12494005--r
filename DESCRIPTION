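Package: omrfocus
Title: Attentional Switching Analysis for Larval Zebrafish Optomotor Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse bout-level optomotor response (OMR)
    behavior of larval zebrafish in coherent-dot assays. Provides a seeded
    generator for bout tables with an engaged/disengaged attention chain gating
    a leaky drift-diffusion decision process, per-trial performance scoring and
    filtering, binomial and directional-persistence null models of baseline
    turning, a truncated Gaussian-gamma mixture that decomposes stimulus-period
    performance into focus (w) and competence (kappa), a gamma-emission hidden
    Markov model with EM fitting and cross-validated state selection, and
    fish-level permutation tests for group differences in fitted parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
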