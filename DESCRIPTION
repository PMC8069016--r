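Package: rutinpk
Title: Population Pharmacokinetics of Rutin and Its Quercetin Conjugates in Rats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the population pharmacokinetics
    of intravenous rutin and of its circulating quercetin conjugates after oral
    dosing, as studied in rat cohorts given the pure flavonoid or a Physalis
    peruviana calyx extract. Implements two-compartment structural models with
    first-order elimination (intravenous bolus; oral double-site delayed
    absorption reproducing the double-peak phenomenon), covariate and
    random-effects population submodels with combined residual error, a
    synthetic study generator emulating the published trial design with LLOQ
    censoring, non-compartmental analysis (trapezoidal AUC, terminal-slope
    selection, MRT, clearance, relative bioavailability), SAEM population
    estimation with importance-sampling likelihood, Wald tests, IWRES
    diagnostics, and visual predictive checks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
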