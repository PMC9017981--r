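Package: myoxalt
Title: Myocardial Oxygen Transport at Maximal Exercise at High Altitude
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A Fick-principle model of oxygen transport to the myocardium
    at maximal exercise during prolonged altitude exposure. Computes
    myocardial venous O2 saturation and partial pressure from
    literature-extracted study data under two maximal-heart-rate
    hypotheses (observed blunting versus sea-level heart rate), converts
    saturations to pressures through a Hill-form oxyhemoglobin
    dissociation curve, and inverts the balance to find the maximal
    altitude compatible with myocardial oxygenation as a function of
    coronary reserve. Includes the bundled literature table, altitude
    trend regressions, a synthetic study-table generator for parameter
    recovery checks, and report and command-line plumbing.
License: MIT + file LICENSE
Encoding: UTF-8
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
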