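Package: clsecretion
Title: Modeling Transcellular Chloride Secretion in Epithelia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates short-circuit chloride secretion across a polarized
    epithelium using a three-pathway compartment model: conductive chloride
    efflux through apical and basolateral channels (chord-conductance currents)
    and electro-neutral chloride uptake by a basolateral cotransporter with
    two-state activation kinetics. Provides the closed-form biexponential
    solution for intracellular chloride and apical current after a step
    stimulus, a stiff-ODE numerical twin, canned stimulation scenarios,
    Ussing-chamber measurement utilities (conductance from constant-current
    pulses, blocker-sensitive conductance differencing), and an estimator
    that recovers the fold-activation of the electro-neutral transporter
    (e.g. NKCC1) from six steady-state measurables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
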