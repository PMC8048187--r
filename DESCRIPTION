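Package: gexpcal
Title: Model-Based Calibration and Quantification for GeXP Multiplex RT-PCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying transcripts measured by GeXP multiplex
    RT-PCR with capillary electrophoresis readout. Implements a kinetic
    forward model of primer-limited reverse transcription and PCR
    amplification, reading and spike-in normalization of fragment peak
    tables, a two-stage shared-slope calibration over log-log dilution
    series with per-run detection limits, quality-control analyses
    (co-amplification linearity, technical-replicate concordance,
    max-normalized time series), and a seedable synthetic-data generator
    that emulates the statistical structure of fragment tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    tools,
    utils
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
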