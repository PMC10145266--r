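#' Configuration for the synthetic tacrolimus cohort generator
#'
#' Builds and validates the full parameterisation of the steady-state cohort
#' simulator: two-locus haplotype frequencies for CYP3A5*3 (rs776746) and
#' CYP3A4*1G (rs2242480), the dose menu, the sampling schedule over one 12-h
#' dosing interval, and the genotype-class pharmacokinetic parameters of a
#' one-compartment first-order-absorption model at steady state.
#'
#' Haplotypes are ordered (A5*1-A4*1G, A5*1-A4*1, A5*3-A4*1G, A5*3-A4*1).
#' The default frequencies place every *1G allele on a CYP3A5*1 background
#' (complete linkage disequilibrium, D' = 1) with allele frequencies 10/28
#' for CYP3A5*1 and 6/28 for CYP3A4*1G, the marginals of a 14-subject
#' lung-transplant cohort.
#'
#' Apparent clearance CL/F is drawn log-normally per subject around a
#' genotype-class geometric mean: CYP3A5 expressers (carriers of at least one
#' *1 allele) around `gm_clf_expresser`, *3/*3 non-expressers around
#' `gm_clf_nonexpresser`. When `vf_expresser`/`vf_nonexpresser` are `NULL`
#' the class apparent volumes are chosen so that the single-dose time of
#' maximum concentration, log(ka/ke)/(ka - ke), equals `target_tmax` at each
#' class geometric-mean clearance.
#'
#' @param n_subjects number of subjects.
#' @param haplotype_freqs numeric length-4 probability vector (order above);
#'   must be non-negative and sum to 1 within 1e-12.
#' @param dose_choices twice-daily dose menu, mg.
#' @param dose_weights sampling weights for `dose_choices`.
#' @param tau dosing interval, h.
#' @param sampling_times sampling schedule, h; strictly increasing within
#'   `[0, tau]`.
#' @param ka first-order absorption rate constant, 1/h.
#' @param gm_clf_expresser,gm_clf_nonexpresser geometric-mean apparent
#'   clearance CL/F, L/h, for CYP3A5 expressers / *3/*3 non-expressers.
#' @param gsd_clf_expresser,gsd_clf_nonexpresser geometric SD of
#'   between-subject clearance per class (>= 1).
#' @param vf_expresser,vf_nonexpresser apparent volume V/F, L, per class;
#'   `NULL` derives them from `target_tmax` (see Details).
#' @param gsd_vf geometric SD of between-subject volume (>= 1).
#' @param prop_error_cv proportional residual-error coefficient of variation
#'   (fraction, e.g. 0.10).
#' @param lloq lower limit of quantification, ng/mL; simulated observations
#'   below it are reported missing with a below-limit flag.
#' @param target_tmax single-dose time of maximum concentration, h, used to
#'   derive default volumes.
#' @param seed integer master seed; per-subject streams are derived from it
#'   so subject k's draws do not depend on `n_subjects`.
#' @return An object of class `sim_config` (a validated named list, with the
#'   derived elimination rate constant `ke_target` and class volumes filled
#'   in).
#' @seealso [simulate_population()], [simulate_genotypes()]
#' @export
sim_config <- function(n_subjects = 14,
                       haplotype_freqs = c(6, 4, 0, 18) / 28,
                       dose_choices = c(0.5, 1, 2, 3),
                       dose_weights = c(0.25, 0.45, 0.20, 0.10),
                       tau = 12,
                       sampling_times = c(0, 0.5, 1, 2, 4, 6, 8, 10, 12),
                       ka = 1.5,
                       gm_clf_expresser = 18.13,
                       gm_clf_nonexpresser = 3.37,
                       gsd_clf_expresser = 1.65,
                       gsd_clf_nonexpresser = 1.54,
                       vf_expresser = NULL,
                       vf_nonexpresser = NULL,
                       gsd_vf = 1.3,
                       prop_error_cv = 0.10,
                       lloq = 0.5,
                       target_tmax = 2,
                       seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    haplotype_freqs = as.numeric(haplotype_freqs),
    dose_choices = as.numeric(dose_choices),
    dose_weights = as.numeric(dose_weights),
    tau = tau,
    sampling_times = as.numeric(sampling_times),
    ka = ka,
    gm_clf_expresser = gm_clf_expresser,
    gm_clf_nonexpresser = gm_clf_nonexpresser,
    gsd_clf_expresser = gsd_clf_expresser,
    gsd_clf_nonexpresser = gsd_clf_nonexpresser,
    vf_expresser = vf_expresser,
    vf_nonexpresser = vf_nonexpresser,
    gsd_vf = gsd_vf,
    prop_error_cv = prop_error_cv,
    lloq = lloq,
    target_tmax = target_tmax,
    seed = as.integer(seed)
  )

  if (cfg$n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  f <- cfg$haplotype_freqs
  if (length(f) != 4L || any(f < 0) || abs(sum(f) - 1) > 1e-12) {
    stop("haplotype_freqs must be 4 non-negative values summing to 1",
         call. = FALSE)
  }
  if (length(cfg$dose_choices) < 1L || any(cfg$dose_choices <= 0)) {
    stop("dose_choices must be positive", call. = FALSE)
  }
  if (length(cfg$dose_weights) != length(cfg$dose_choices) ||
      any(cfg$dose_weights < 0) || sum(cfg$dose_weights) <= 0) {
    stop("dose_weights must be non-negative and match dose_choices",
         call. = FALSE)
  }
  if (!is.finite(cfg$tau) || cfg$tau <= 0) stop("tau must be > 0", call. = FALSE)
  st <- cfg$sampling_times
  if (length(st) < 2L || any(diff(st) <= 0) || st[1] < 0 || st[length(st)] > cfg$tau) {
    stop("sampling_times must be strictly increasing within [0, tau]",
         call. = FALSE)
  }
  if (cfg$ka <= 0) stop("ka must be > 0", call. = FALSE)
  for (nm in c("gm_clf_expresser", "gm_clf_nonexpresser")) {
    if (cfg[[nm]] <= 0) stop(nm, " must be > 0", call. = FALSE)
  }
  for (nm in c("gsd_clf_expresser", "gsd_clf_nonexpresser", "gsd_vf")) {
    if (cfg[[nm]] < 1) stop(nm, " must be >= 1", call. = FALSE)
  }
  if (cfg$prop_error_cv < 0) stop("prop_error_cv must be >= 0", call. = FALSE)
  if (cfg$lloq < 0) stop("lloq must be >= 0", call. = FALSE)

  # elimination rate giving the target single-dose tmax at this ka;
  # tmax(ke) = log(ka/ke)/(ka - ke) is decreasing in ke on (0, ka)
  ke <- stats::uniroot(
    function(k) log(cfg$ka / k) / (cfg$ka - k) - cfg$target_tmax,
    interval = c(1e-6, cfg$ka * (1 - 1e-6)), tol = 1e-12
  )$root
  cfg$ke_target <- ke
  if (is.null(cfg$vf_expresser)) cfg$vf_expresser <- cfg$gm_clf_expresser / ke
  if (is.null(cfg$vf_nonexpresser)) cfg$vf_nonexpresser <- cfg$gm_clf_nonexpresser / ke
  if (cfg$vf_expresser <= 0 || cfg$vf_nonexpresser <= 0) {
    stop("apparent volumes must be > 0", call. = FALSE)
  }

  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic tacrolimus cohort configuration\n")
  cat(sprintf("  subjects: %d, tau: %g h, seed: %d\n",
              x$n_subjects, x$tau, x$seed))
  cat(sprintf("  sampling times (h): %s\n",
              paste(x$sampling_times, collapse = ", ")))
  cat(sprintf("  haplotype freqs (A5*1-A4*1G, A5*1-A4*1, A5*3-A4*1G, A5*3-A4*1): %s\n",
              paste(signif(x$haplotype_freqs, 4), collapse = ", ")))
  cat(sprintf("  GM CL/F (L/h): expresser %.2f (GSD %.2f), non-expresser %.2f (GSD %.2f)\n",
              x$gm_clf_expresser, x$gsd_clf_expresser,
              x$gm_clf_nonexpresser, x$gsd_clf_nonexpresser))
  cat(sprintf("  ka %.3g 1/h, V/F %.1f / %.1f L (GSD %.2f), residual CV %.0f%%, LLOQ %.2g ng/mL\n",
              x$ka, x$vf_expresser, x$vf_nonexpresser, x$gsd_vf,
              100 * x$prop_error_cv, x$lloq))
  invisible(x)
}

#' Read a simulator configuration from a flat key-value file
#'
#' Parses lines of the form `key = value` (comma-separated values for vector
#' fields, `#` comments allowed) and passes them to [sim_config()]; keys not
#' present keep their defaults.
#'
#' @param path file path.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("cannot parse config line: ", ln, call. = FALSE)
    }
    key <- trimws(parts[1])
    vals <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    if (any(is.na(num))) {
      stop("non-numeric value for config key '", key, "'", call. = FALSE)
    }
    args[[key]] <- num
  }
  unknown <- setdiff(names(args), names(formals(sim_config)))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, args)
}
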