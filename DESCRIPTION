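Package: ocplasticity
Title: Dopamine-Gated Hebbian Plasticity During Operant Conditioning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates learning of an appetitive operant conditioning task
    (lever press for food) with a rate-based cortico-basal-ganglia network:
    a temporal-difference model of midbrain dopamine emits reward prediction
    errors that open Hebbian or anti-Hebbian gating windows over prefrontal
    and basal-ganglia/premotor synapses. Runs ensembles of models, tracks
    performance and the per-trial sum of absolute synaptic change (a
    plasticity read-out), and compares its learning-stage dynamics against
    plasticity-related gene expression (BDNF, CREB, Synapsin I, CamKII and
    immediate early genes) through a synthetic quantitative RT-PCR data
    generator and the matching ANOVA/Tukey statistical pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
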