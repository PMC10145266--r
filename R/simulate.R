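# Haplotype table shared by the genotype and population simulators.
# Order: (A5*1-A4*1G, A5*1-A4*1, A5*3-A4*1G, A5*3-A4*1).
.hap_alleles <- data.frame(
  cyp3a5 = c("*1", "*1", "*3", "*3"),
  cyp3a4 = c("*1G", "*1", "*1G", "*1"),
  stringsAsFactors = FALSE
)

# Derive a per-subject seed from the master seed so that subject k's random
# stream is identical whatever n_subjects is. Kept below 2^31 - 1.
.subject_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483647) * 48271 + 16807 * k) %% 2147483647L
}

.genotype_string <- function(a1, a2, order) {
  i <- match(c(a1, a2), order)
  paste(order[sort(i)], collapse = "/")
}

# Draw one subject's two haplotypes plus dose/PK randomness from its own
# stream. Draw order is fixed: hap1, hap2, dose, z_clf, z_vf, residuals.
.subject_draw <- function(cfg, k, n_times) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.subject_seed(cfg$seed, k))
  haps <- sample.int(4L, 2L, replace = TRUE, prob = cfg$haplotype_freqs)
  dose <- cfg$dose_choices[sample.int(length(cfg$dose_choices), 1L,
                                      prob = cfg$dose_weights)]
  z_clf <- stats::rnorm(1)
  z_vf <- stats::rnorm(1)
  eps <- stats::rnorm(n_times)
  list(haps = haps, dose = dose, z_clf = z_clf, z_vf = z_vf, eps = eps)
}

#' Simulate two-locus CYP3A genotypes
#'
#' Each subject receives two haplotypes drawn i.i.d. from the four-haplotype
#' frequency vector (order A5*1-A4*1G, A5*1-A4*1, A5*3-A4*1G, A5*3-A4*1),
#' so linkage disequilibrium between CYP3A5*3 and CYP3A4*1G is controlled
#' directly by the haplotype frequencies and each locus is in
#' Hardy-Weinberg proportions marginally.
#'
#' @param n number of subjects (>= 1).
#' @param haplotype_freqs length-4 probability vector, see [sim_config()].
#' @param seed integer seed; subject k's genotype depends only on
#'   `(seed, k)`, not on `n`.
#' @return A data.frame with columns `subject_id`, `cyp3a5` (one of
#'   `*1/*1`, `*1/*3`, `*3/*3`) and `cyp3a4` (one of `*1/*1`, `*1/*1G`,
#'   `*1G/*1G`).
#' @export
simulate_genotypes <- function(n, haplotype_freqs = c(6, 4, 0, 18) / 28,
                               seed = 1L) {
  if (length(n) != 1L || !is.finite(n) || n < 1) {
    stop("n must be a single integer >= 1", call. = FALSE)
  }
  f <- as.numeric(haplotype_freqs)
  if (length(f) != 4L || any(f < 0) || abs(sum(f) - 1) > 1e-12) {
    stop("haplotype_freqs must be 4 non-negative values summing to 1",
         call. = FALSE)
  }
  cfg <- list(seed = as.integer(seed), haplotype_freqs = f,
              dose_choices = 1, dose_weights = 1)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    d <- .subject_draw(cfg, k, 0L)
    h <- .hap_alleles[d$haps, ]
    out[[k]] <- data.frame(
      subject_id = sprintf("S%03d", k),
      cyp3a5 = .genotype_string(h$cyp3a5[1], h$cyp3a5[2], c("*1", "*3")),
      cyp3a4 = .genotype_string(h$cyp3a4[1], h$cyp3a4[2], c("*1", "*1G")),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Steady-state concentration of a one-compartment oral-absorption model
#'
#' Whole-blood concentration at time `t` within a dosing interval of length
#' `tau` under repeated dosing to steady state, first-order absorption and
#' elimination:
#' \deqn{C(t) = \frac{1000\,D\,k_a}{V/F\,(k_a-k_e)}\left[
#'   \frac{e^{-k_e t}}{1-e^{-k_e\tau}} - \frac{e^{-k_a t}}{1-e^{-k_a\tau}}
#' \right]}
#' with \eqn{k_e = (CL/F)/(V/F)}; the factor 1000 converts mg/L to ng/mL.
#' The profile is periodic, `C(0) == C(tau)`, and its integral over one
#' interval is exactly `1000 * dose / clf`.
#'
#' @param t time since dose, h; vectorised, each value in `[0, tau]`.
#' @param dose dose per interval, mg.
#' @param ka absorption rate constant, 1/h.
#' @param clf apparent clearance CL/F, L/h.
#' @param vf apparent volume V/F, L.
#' @param tau dosing interval, h.
#' @return Concentration(s), ng/mL.
#' @details The flip-flop degenerate case `ka == ke` is rejected rather than
#'   handled by its analytic limit.
#' @export
steady_state_conc <- function(t, dose, ka, clf, vf, tau = 12) {
  if (any(!is.finite(t)) || any(t < 0) || any(t > tau)) {
    stop("t must lie within [0, tau]", call. = FALSE)
  }
  for (v in list(dose = dose, ka = ka, clf = clf, vf = vf, tau = tau)) {
    if (length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("dose, ka, clf, vf and tau must be positive scalars", call. = FALSE)
    }
  }
  ke <- clf / vf
  if (abs(ka - ke) <= 1e-10 * ka) {
    stop("ka equals ke (flip-flop degenerate case); not supported",
         call. = FALSE)
  }
  a <- 1000 * dose * ka / (vf * (ka - ke))
  a * (exp(-ke * t) / (1 - exp(-ke * tau)) -
         exp(-ka * t) / (1 - exp(-ka * tau)))
}

#' Simulate a steady-state tacrolimus cohort
#'
#' Generates genotypes, doses, subject-level pharmacokinetic parameters and
#' observed concentration profiles on the configured sampling schedule.
#' Subject CL/F is log-normal around the genotype-class geometric mean
#' (CYP3A5 *3/*3 non-expressers vs. expressers), V/F log-normal around the
#' class volume, and a multiplicative log-normal residual error with the
#' configured CV is applied to each sampled concentration. Observations
#' below the LLOQ are reported as missing with `blq = TRUE`.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `tac_cohort` with components
#'   \describe{
#'     \item{truth}{data.frame: `subject_id`, `cyp3a5`, `cyp3a4`,
#'       `true_clf` (L/h), `true_vf` (L), `dose` (mg).}
#'     \item{conc}{long data.frame: `subject_id`, `time_h`,
#'       `conc_ng_ml` (NA when below LLOQ), `blq`.}
#'     \item{genotypes}{data.frame `subject_id`, `cyp3a5`, `cyp3a4`.}
#'     \item{dose}{data.frame `subject_id`, `dose_mg`.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("config must be a sim_config object", call. = FALSE)
  }
  cfg <- config
  st <- cfg$sampling_times
  nt <- length(st)
  sdlog_e <- sqrt(log(1 + cfg$prop_error_cv^2))

  truth <- vector("list", cfg$n_subjects)
  conc <- vector("list", cfg$n_subjects)
  for (k in seq_len(cfg$n_subjects)) {
    d <- .subject_draw(cfg, k, nt)
    h <- .hap_alleles[d$haps, ]
    g5 <- .genotype_string(h$cyp3a5[1], h$cyp3a5[2], c("*1", "*3"))
    g4 <- .genotype_string(h$cyp3a4[1], h$cyp3a4[2], c("*1", "*1G"))
    nonexpr <- g5 == "*3/*3"
    gm_clf <- if (nonexpr) cfg$gm_clf_nonexpresser else cfg$gm_clf_expresser
    gsd_clf <- if (nonexpr) cfg$gsd_clf_nonexpresser else cfg$gsd_clf_expresser
    vf_class <- if (nonexpr) cfg$vf_nonexpresser else cfg$vf_expresser
    clf_k <- gm_clf * exp(d$z_clf * log(gsd_clf))
    vf_k <- vf_class * exp(d$z_vf * log(cfg$gsd_vf))
    ctrue <- steady_state_conc(st, d$dose, cfg$ka, clf_k, vf_k, cfg$tau)
    cobs <- ctrue * exp(d$eps * sdlog_e)
    blq <- cobs < cfg$lloq
    id <- sprintf("S%03d", k)
    truth[[k]] <- data.frame(
      subject_id = id, cyp3a5 = g5, cyp3a4 = g4,
      true_clf = clf_k, true_vf = vf_k, dose = d$dose,
      stringsAsFactors = FALSE
    )
    conc[[k]] <- data.frame(
      subject_id = id, time_h = st,
      conc_ng_ml = ifelse(blq, NA_real_, cobs), blq = blq,
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, truth)
  out <- list(
    truth = truth,
    conc = do.call(rbind, conc),
    genotypes = truth[, c("subject_id", "cyp3a5", "cyp3a4")],
    dose = data.frame(subject_id = truth$subject_id, dose_mg = truth$dose,
                      stringsAsFactors = FALSE),
    config = cfg
  )
  rownames(out$truth) <- rownames(out$conc) <- rownames(out$genotypes) <-
    rownames(out$dose) <- NULL
  class(out) <- "tac_cohort"
  out
}

#' @export
print.tac_cohort <- function(x, ...) {
  cat(sprintf("Synthetic tacrolimus cohort: %d subjects, %d samples (%d BLQ)\n",
              nrow(x$truth), nrow(x$conc), sum(x$conc$blq)))
  tab <- table(x$truth$cyp3a5)
  cat("  CYP3A5 genotypes:",
      paste(sprintf("%s n=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write cohort CSV files
#'
#' Emits the three analysis inputs plus the ground truth:
#' `concentrations.csv` (`subject_id,time_h,conc_ng_ml,blq`),
#' `doses.csv` (`subject_id,dose_mg`), `genotypes.csv`
#' (`subject_id,cyp3a5,cyp3a4`) and `truth.csv`.
#'
#' @param cohort a `tac_cohort` from [simulate_population()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "tac_cohort")) {
    stop("cohort must be a tac_cohort", call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    conc = file.path(dir, "concentrations.csv"),
    dose = file.path(dir, "doses.csv"),
    genotypes = file.path(dir, "genotypes.csv"),
    truth = file.path(dir, "truth.csv")
  )
  utils::write.csv(cohort$conc, paths["conc"], row.names = FALSE)
  utils::write.csv(cohort$dose, paths["dose"], row.names = FALSE)
  utils::write.csv(cohort$genotypes, paths["genotypes"], row.names = FALSE)
  utils::write.csv(cohort$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}
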