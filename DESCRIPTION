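Package: knallgas
Title: Quantitative Physiology of Hydrogen-Oxidizing Chemolithoautotrophs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative physiology of aerobic, H2-oxidizing
    chemolithoautotrophs ("Knallgas" bacteria). Implements progress-curve
    estimation of whole-cell Michaelis-Menten kinetics (apparent Vmax and Ks)
    from membrane-inlet mass spectrometry (MIMS) substrate-depletion traces,
    steady-state chemostat carbon and nitrogen mass balances (biomass yield on
    H2, CO2 fixed per H2, the excreted versus assimilated partition of fixed
    carbon, and the N:C ratio of excreted organics), and exometabolome
    accounting: untargeted LC-MS feature filtering, isotope and in-source
    fragment flagging, accurate-mass amino-acid annotation, calibration-curve
    quantification, and compound-level carbon closure against total organic
    carbon. Seeded synthetic-data generators emulate MIMS traces, chemostat
    records and LC-MS feature tables so every stage is testable without
    instrument data.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
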