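Package: vipertherm
Title: Thermal Ecology and Climate-Warming Activity Budgets for Alpine Vipers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the thermoregulation of ectotherms from
    thermal-gradient trials, field body temperatures and operative-temperature
    logger series. Estimates preferred body temperature (Tp) and the set-point
    range (Tset) by a normalized kernel-density, half-maximum procedure;
    computes the classic thermoregulation index suite (accuracy db, habitat
    thermal quality de, effectiveness E and I, thermal exploitation Ex) with
    percentile-bootstrap confidence intervals; synthesizes hourly operative
    temperature over a year from monthly climate means and counts annual
    activity-restriction hours (hr) under current and future climate-scenario
    offsets; tests for phylogenetic signal in population traits (Blomberg's K
    with permutation test, Pagel's lambda by maximum likelihood); and runs the
    accompanying population-level statistics. A seeded synthetic-data
    generator emulating a five-population alpine viper study makes the whole
    pipeline reproducible without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    multcomp,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
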