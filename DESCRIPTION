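Package: tacropk
Title: Tacrolimus Dosing-Interval Pharmacokinetics, Limited Sampling and
    CYP3A Pharmacogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-compartmental analysis of intensively sampled 12-hour
    tacrolimus concentration profiles in the early period after lung
    transplantation: linear-up log-down trapezoidal AUC, apparent clearance
    and dose-normalised exposure metrics with geometric summaries;
    single-point limited-sampling-strategy development with Sheiner-Beal
    predictive-performance metrics (MPE, MAE, F15/F20/F25) and a clinical
    acceptability rule; CYP3A5*3 and CYP3A4*1G pharmacogenetic statistics
    (carrier classification, Hardy-Weinberg testing, EM haplotype and
    linkage-disequilibrium estimation, ANOVA on log-scale parameters);
    evaluation of published covariate models of tacrolimus clearance; and a
    steady-state one-compartment cohort simulator so the whole pipeline is
    testable without patient-level data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
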