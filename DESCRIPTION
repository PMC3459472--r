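Package: sanpace
Title: Beta-Adrenergic Modulation of Rabbit Sinoatrial Node Pacemaker Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic ODE models of central and peripheral rabbit sinoatrial
    node (SAN) pacemaker cells, together with a six-equation isoprenaline (ISO)
    concentration-response layer acting on I_CaL, I_f, I_Kr, I_Ks, I_st and
    intracellular Ca2+ handling. Provides a stiff-ODE simulation engine
    (compiled right-hand sides integrated with 'deSolve'), action-potential
    feature extraction (cycle length, rate, maximum diastolic potential,
    overshoot, APD50/APD90, dV/dt max, Ca2+ transient levels), dose-response
    and single-action dissection experiments, Hill-curve fitting for
    dose-response point tables, and ggplot2 visualisations. All tabular results
    are returned as tibbles so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    readr,
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
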