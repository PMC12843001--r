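Package: damsim
Title: Simulation of Dual-Anaplerotic Metabolic Oscillations in Pancreatic Beta Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A driven four-pool model of oscillatory carbon redistribution in
    pancreatic beta cells, coupling glycolysis, the two halves of the TCA
    cycle and the GABA shunt. Prescribed calcium and ATP waveforms force five
    power-law fluxes between coarse-grained metabolite pools; the package
    integrates the resulting ODE system, extracts per-period oscillation
    amplitudes and extremum phases, annotates oxidative versus cataplerotic
    phases, and provides parameter and phase-offset sweep procedures together
    with an extended variant in which the glycolytic pool is dynamic with
    phosphofructokinase-regulated influx. Results are tidy tibbles with
    ggplot2 plotting methods; a thin command-line interface and YAML
    configuration support scripted runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
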