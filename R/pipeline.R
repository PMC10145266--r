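# Report-cell formatting helpers. Numeric cells are rounded half-even to
# two decimals (R's round()); machine-readable CSVs keep full precision.

#' Significance stars for a p-value
#'
#' `***` for p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05, otherwise
#' an empty string.
#'
#' @param p p-value(s).
#' @param levels thresholds, decreasing strictness not required; defaults
#'   `c(0.05, 0.01, 0.001)`.
#' @return character vector of star strings.
#' @export
p_stars <- function(p, levels = c(0.05, 0.01, 0.001)) {
  levels <- sort(levels, decreasing = TRUE)
  vapply(p, function(pi) {
    if (is.na(pi)) return("")
    strrep("*", sum(pi <= levels))
  }, character(1))
}

.fmt_gm_cell <- function(gm, gsd, cv_pct, stars = "") {
  cell <- sprintf("%.2f ± %.2f (%.2f)", round(gm, 2), round(gsd, 2),
                  round(cv_pct, 2))
  if (nzchar(stars)) paste(cell, stars) else cell
}

.fmt_median_range <- function(values) {
  sprintf("%.2f (%.2f–%.2f)", round(stats::median(values), 2),
          round(min(values), 2), round(max(values), 2))
}

.table2_params <- c(
  cmax = "Cmax (ng/mL)", cmax_per_dose = "Cmax/D (ng/mL)",
  cmin = "Cmin (ng/mL)", cmin_per_dose = "Cmin/D (ng/mL)",
  clf = "CL/F (L/h)", auc_0_12 = "AUC0-12h (ng.h/mL)",
  auc_per_dose = "AUC0-12h/D (ng.h/mL)"
)

# Genotype-stratified geometric summary with ANOVA p per parameter.
.stratified_summary <- function(nca, classes) {
  groups <- split(seq_len(nrow(nca)), classes)
  if (length(groups) < 2L || any(lengths(groups) < 2L)) {
    stop("each genotype class needs at least 2 subjects for stratification",
         call. = FALSE)
  }
  rows <- lapply(names(.table2_params), function(par) {
    v <- nca[[par]]
    cmp <- compare_groups(v, classes)
    out <- data.frame(parameter = .table2_params[[par]],
                      stringsAsFactors = FALSE)
    all_gs <- geo_summary(v)
    out$all_gm <- all_gs$gm; out$all_gsd <- all_gs$gsd
    out$all_cv <- all_gs$cv_pct
    for (g in names(groups)) {
      gs <- geo_summary(v[groups[[g]]])
      out[[paste0(g, "_gm")]] <- gs$gm
      out[[paste0(g, "_gsd")]] <- gs$gsd
      out[[paste0(g, "_cv")]] <- gs$cv_pct
    }
    out$p <- cmp$p
    out$stars <- p_stars(cmp$p)
    out
  })
  do.call(rbind, rows)
}

#' Run the full tacrolimus pharmacokinetic analysis pipeline
#'
#' Orchestrates the stages of the cohort analysis: load (or simulate) the
#' concentration, dosing and genotype tables; per-subject non-compartmental
#' analysis; genotype carrier classification and CYP3A5-stratified summary
#' with ANOVA on log-transformed parameters; Hardy-Weinberg tests and
#' two-locus linkage-disequilibrium estimation; the single-point
#' limited-sampling scan; and the published covariate-model comparison at a
#' typical-patient covariate profile. All tables are written as CSV to
#' `out_dir` (plus a run log with the seed and package version) and returned
#' invisibly; identical configuration and seed give byte-identical outputs.
#'
#' @param config a list with either `sim` (a [sim_config()]) or the paths
#'   `conc_file`, `dose_file`, `genotype_file`; optional `out_dir` (no files
#'   written when `NULL`), `seed` (overrides the simulator seed),
#'   `thresholds` (F thresholds, default `c(15, 20, 25)`), `bounds`
#'   (acceptability bounds), and `typical` (named list of covariates for the
#'   published-model comparison, default `list(wt = 64.5, hct = 30, dd = 2,
#'   pot = 3.5, voriconazole = TRUE, cyp3a5_expresser = FALSE)`).
#' @return An object of class `tac_report`: list with `nca`, `table2`
#'   (stratified summary), `hwe` (per locus), `ld`, `lss` (an `lss_scan`),
#'   `table4` (published-model comparison), `genotypes` (with carrier
#'   classes), `truth` (when simulated) and `config`.
#' @export
run_pipeline <- function(config) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  thresholds <- config$thresholds %||% c(15, 20, 25)
  bounds <- config$bounds %||% c(mpe = 15, mae = 30,
                                 f15 = 40, f20 = 45, f25 = 50)
  typical <- utils::modifyList(
    list(wt = 64.5, hct = 30, dd = 2, pot = 3.5,
         voriconazole = TRUE, cyp3a5_expresser = FALSE),
    config$typical %||% list())

  truth <- NULL
  if (!is.null(config$sim)) {
    sim <- config$sim
    if (!inherits(sim, "sim_config")) {
      stop("config$sim must be a sim_config", call. = FALSE)
    }
    if (!is.null(config$seed)) {
      sim$seed <- as.integer(config$seed)
    }
    cohort <- simulate_population(sim)
    conc <- cohort$conc; dose <- cohort$dose; geno <- cohort$genotypes
    truth <- cohort$truth
  } else {
    for (f in c("conc_file", "dose_file", "genotype_file")) {
      if (is.null(config[[f]])) {
        stop("config needs either $sim or the three input paths; missing ",
             f, call. = FALSE)
      }
      if (!file.exists(config[[f]])) {
        stop("input file not found: ", config[[f]], call. = FALSE)
      }
    }
    conc <- utils::read.csv(config$conc_file, stringsAsFactors = FALSE)
    dose <- utils::read.csv(config$dose_file, stringsAsFactors = FALSE)
    geno <- utils::read.csv(config$genotype_file, stringsAsFactors = FALSE)
  }

  ids <- sort(unique(conc$subject_id))
  for (nm in list(c("dosing", "dose"), c("genotype", "geno"))) {
    tab <- get(nm[2])
    missing_ids <- setdiff(ids, tab$subject_id)
    if (length(missing_ids)) {
      stop("subject(s) missing from the ", nm[1], " table: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
  }

  nca <- nca_cohort(conc, dose)
  geno <- classify_carriers(geno)
  classes <- geno$cyp3a5_class[match(nca$subject_id, geno$subject_id)]
  table2 <- .stratified_summary(nca, classes)

  counts5 <- as.integer(table(factor(geno$cyp3a5, levels = .cyp3a5_levels)))
  counts4 <- as.integer(table(factor(geno$cyp3a4, levels = .cyp3a4_levels)))
  hwe <- list(cyp3a5 = hwe_test(counts5), cyp3a4 = hwe_test(counts4))
  ld <- em_haplotypes(geno)

  lss <- lss_scan(conc, nca, thresholds = thresholds, bounds = bounds)

  own <- geo_summary(nca$clf)$gm
  table4 <- comparison_table(own, wt = typical$wt, hct = typical$hct,
                             dd = typical$dd, pot = typical$pot,
                             voz = typical$voz,
                             cyp3a5_expresser = typical$cyp3a5_expresser,
                             voriconazole = typical$voriconazole)

  report <- list(nca = nca, table2 = table2, hwe = hwe, ld = ld, lss = lss,
                 table4 = table4, genotypes = geno, truth = truth,
                 config = config)
  class(report) <- "tac_report"

  if (!is.null(config$out_dir)) {
    dir <- config$out_dir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(nca, file.path(dir, "nca_per_subject.csv"),
                     row.names = FALSE)
    utils::write.csv(table2, file.path(dir, "stratified_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(lss$table, file.path(dir, "lss_scan.csv"),
                     row.names = FALSE)
    utils::write.csv(table4, file.path(dir, "published_models.csv"),
                     row.names = FALSE)
    hwe_df <- do.call(rbind, lapply(names(hwe), function(l) {
      h <- hwe[[l]]
      data.frame(locus = l, n_hom_ref = h$observed[1],
                 n_het = h$observed[2], n_hom_alt = h$observed[3],
                 chi2 = h$chi2, p = h$p, method = h$method,
                 stringsAsFactors = FALSE)
    }))
    if (ld$ok) {
      hwe_df$d_prime <- ld$d_prime
      hwe_df$ld_r2 <- ld$r2
    }
    utils::write.csv(hwe_df, file.path(dir, "pgx_report.csv"),
                     row.names = FALSE)
    seed_used <- if (!is.null(config$sim)) config$sim$seed else config$seed
    writeLines(c(
      sprintf("tacropk version: %s",
              as.character(utils::packageVersion("tacropk"))),
      sprintf("seed: %s", if (is.null(seed_used)) "none" else seed_used),
      sprintf("n_subjects: %d", nrow(nca))
    ), file.path(dir, "run_log.txt"))
  }
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tac_report <- function(x, ...) {
  cat(sprintf("Tacrolimus PK analysis report: %d subjects\n", nrow(x$nca)))
  cat("\nGenotype-stratified summary (CYP3A5):\n")
  print(render_tables(x)$table2, row.names = FALSE)
  cat("\nLimited-sampling scan:\n")
  print(x$lss)
  cat("\nPublished-model comparison (adjusted CL/F, L/h):\n")
  t4 <- x$table4
  t4$adjusted_clf <- round(t4$adjusted_clf, 2)
  t4$ratio_to_cohort <- round(t4$ratio_to_cohort, 2)
  print(t4, row.names = FALSE)
  invisible(x)
}

#' Render report tables as formatted text cells
#'
#' Formats the stratified summary in the conventional presentation:
#' `GM (ng/mL or L/h) ± GSD (CV%)` cells with significance stars for
#' log-scale parameters, `median (min–max)` for Tmax, all rounded
#' half-even to 2 decimals.
#'
#' @param report a `tac_report` from [run_pipeline()].
#' @return list with `table2` (formatted stratified summary including the
#'   Tmax row) and `table3` (formatted limited-sampling table).
#' @export
render_tables <- function(report) {
  if (!inherits(report, "tac_report")) {
    stop("report must be a tac_report", call. = FALSE)
  }
  t2 <- report$table2
  grp_cols <- setdiff(
    unique(sub("_(gm|gsd|cv)$", "",
               grep("_(gm|gsd|cv)$", names(t2), value = TRUE))),
    "all")
  out2 <- data.frame(parameter = t2$parameter, stringsAsFactors = FALSE)
  out2$all <- mapply(.fmt_gm_cell, t2$all_gm, t2$all_gsd, t2$all_cv)
  for (g in grp_cols) {
    stars <- if (g == grp_cols[length(grp_cols)]) t2$stars else ""
    out2[[g]] <- mapply(.fmt_gm_cell, t2[[paste0(g, "_gm")]],
                        t2[[paste0(g, "_gsd")]], t2[[paste0(g, "_cv")]],
                        stars)
  }
  # Tmax row: median (range), overall and per class
  classes <- report$genotypes$cyp3a5_class[
    match(report$nca$subject_id, report$genotypes$subject_id)]
  tmax_row <- data.frame(parameter = "Tmax (h)",
                         all = .fmt_median_range(report$nca$tmax),
                         stringsAsFactors = FALSE)
  for (g in grp_cols) {
    tmax_row[[g]] <- .fmt_median_range(report$nca$tmax[classes == g])
  }
  out2 <- rbind(out2, tmax_row)

  t3 <- report$lss$table
  thr <- report$lss$thresholds
  out3 <- data.frame(
    time_h = t3$time_h,
    conc = sprintf("%.2f ± %.2f", round(t3$gm, 2), round(t3$gsd, 2)),
    r2 = round(t3$r2, 3),
    mpe = sprintf("%.0f (%.0f–%.0f)", t3$mpe_median, t3$mpe_min,
                  t3$mpe_max),
    mae = sprintf("%.0f (%.0f–%.0f)", t3$mae_median, t3$mae_min,
                  t3$mae_max),
    stringsAsFactors = FALSE
  )
  for (k in thr) {
    out3[[paste0("n_gt", k)]] <- t3[[paste0("n_exceed_", k)]]
    out3[[paste0("f", k)]] <- round(t3[[paste0("f", k)]])
  }
  out3$acceptable <- t3$acceptable
  list(table2 = out2, table3 = out3)
}
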