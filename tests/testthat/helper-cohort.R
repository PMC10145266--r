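# Shared fixtures: all synthetic, built in code at test time.

# Default study-like configuration (14 subjects, 9-point schedule,
# genotype-specific clearance); override fields as needed.
study_config <- function(...) {
  sim_config(...)
}

# A constant-concentration profile whose linear-trapezoid AUC is exact:
# conc * 12 over the standard 9-point grid.
flat_profile <- function(conc, dose = 1, id = "flat") {
  times <- c(0, 0.5, 1, 2, 4, 6, 8, 10, 12)
  conc_profile(id, times, rep(conc, length(times)), dose)
}

# Noise-free cohort: no between-subject or residual variability.
noiseless_config <- function(...) {
  sim_config(gsd_clf_expresser = 1, gsd_clf_nonexpresser = 1,
             gsd_vf = 1, prop_error_cv = 0, ...)
}
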