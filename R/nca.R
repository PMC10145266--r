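#' Dosing-interval concentration profile
#'
#' Container for one subject's concentration-time series over a single
#' dosing interval, with the dose administered in that interval. Missing
#' concentrations (below the limit of quantification) are allowed and are
#' excluded from analysis.
#'
#' @param subject_id subject identifier.
#' @param times sampling times, h; strictly increasing, non-negative.
#' @param concs whole-blood concentrations, ng/mL; `NA` for BLQ; all
#'   non-missing values must be >= 0; at least 3 non-missing points.
#' @param dose dose administered per interval, mg; > 0.
#' @return An object of class `conc_profile`.
#' @export
conc_profile <- function(subject_id, times, concs, dose) {
  times <- as.numeric(times)
  concs <- as.numeric(concs)
  if (length(times) != length(concs)) {
    stop("times and concs must have equal length", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(times < 0) || any(diff(times) <= 0)) {
    stop("times must be finite, non-negative and strictly increasing",
         call. = FALSE)
  }
  ok <- !is.na(concs)
  if (sum(ok) < 3L) {
    stop("profile needs at least 3 non-missing concentrations", call. = FALSE)
  }
  if (any(concs[ok] < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (length(dose) != 1L || !is.finite(dose) || dose <= 0) {
    stop("dose must be a positive scalar (mg)", call. = FALSE)
  }
  structure(list(subject_id = subject_id, times = times, concs = concs,
                 dose = dose),
            class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("Concentration profile %s: dose %g mg, %d/%d observed points\n",
              x$subject_id, x$dose, sum(!is.na(x$concs)), length(x$times)))
  invisible(x)
}

#' Linear-up log-down trapezoidal AUC
#'
#' Area under the concentration-time curve computed segment by segment:
#' the linear trapezoid \eqn{(C_1+C_2)\Delta t/2} when the concentration is
#' rising or flat (or either endpoint is zero), and the log trapezoid
#' \eqn{(C_1-C_2)\Delta t/\ln(C_1/C_2)} when it is falling with both
#' endpoints positive.
#'
#' @param times sampling times, h; strictly increasing, no missing values.
#' @param concs concentrations, ng/mL; same length, no missing values,
#'   all >= 0.
#' @return AUC in ng.h/mL.
#' @export
auc_linuplogdown <- function(times, concs) {
  times <- as.numeric(times)
  concs <- as.numeric(concs)
  if (length(times) != length(concs)) {
    stop("times and concs must have equal length", call. = FALSE)
  }
  if (anyNA(times) || anyNA(concs)) {
    stop("missing values are not allowed; drop BLQ points first",
         call. = FALSE)
  }
  if (length(times) < 2L) {
    stop("need at least 2 points to compute an AUC", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(concs < 0)) stop("concentrations must be >= 0", call. = FALSE)

  n <- length(times)
  c1 <- concs[-n]; c2 <- concs[-1]
  dt <- diff(times)
  logdown <- c2 < c1 & c2 > 0              # falling with positive endpoints
  seg <- numeric(n - 1L)
  seg[!logdown] <- (c1[!logdown] + c2[!logdown]) / 2 * dt[!logdown]
  if (any(logdown)) {
    seg[logdown] <- (c1[logdown] - c2[logdown]) /
      log(c1[logdown] / c2[logdown]) * dt[logdown]
  }
  sum(seg)
}

#' Non-compartmental analysis of one dosing-interval profile
#'
#' Computes the dosing-interval AUC by the linear-up log-down trapezoidal
#' rule, the observed maximum and minimum concentrations and the time of the
#' maximum (earliest on ties), apparent clearance
#' `CL/F (L/h) = 1000 * dose (mg) / AUC (ng.h/mL)`, and the exposure metrics
#' normalised to a 1-mg dose. BLQ (missing) points are excluded.
#'
#' @param profile a [conc_profile()].
#' @return An object of class `nca_result`: list with `subject_id`, `dose`,
#'   `auc_0_12`, `cmax`, `cmin`, `tmax`, `clf`, `auc_per_dose`,
#'   `cmax_per_dose`, `cmin_per_dose`, `n_points`.
#' @export
run_nca <- function(profile) {
  if (!inherits(profile, "conc_profile")) {
    stop("profile must be a conc_profile", call. = FALSE)
  }
  ok <- !is.na(profile$concs)
  if (sum(ok) < 3L) {
    stop("fewer than 3 usable concentrations", call. = FALSE)
  }
  tt <- profile$times[ok]
  cc <- profile$concs[ok]
  auc <- auc_linuplogdown(tt, cc)
  if (auc <= 0) {
    stop("degenerate profile: AUC is zero", call. = FALSE)
  }
  cmax <- max(cc)
  cmin <- min(cc)
  tmax <- tt[which.max(cc)]   # which.max returns the earliest tie
  clf <- 1000 * profile$dose / auc
  res <- list(
    subject_id = profile$subject_id,
    dose = profile$dose,
    auc_0_12 = auc,
    cmax = cmax,
    cmin = cmin,
    tmax = tmax,
    clf = clf,
    auc_per_dose = auc / profile$dose,
    cmax_per_dose = cmax / profile$dose,
    cmin_per_dose = cmin / profile$dose,
    n_points = sum(ok)
  )
  class(res) <- "nca_result"
  res
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf(
    "NCA %s: AUC0-12 %.2f ng.h/mL, Cmax %.2f, Cmin %.2f ng/mL, Tmax %g h, CL/F %.2f L/h\n",
    x$subject_id, x$auc_0_12, x$cmax, x$cmin, x$tmax, x$clf))
  invisible(x)
}

#' Non-compartmental analysis of a whole cohort
#'
#' Applies [run_nca()] to every subject of a long concentration table paired
#' with a dosing table and returns one row per subject.
#'
#' @param conc data.frame with `subject_id`, `time_h`, `conc_ng_ml`
#'   (optionally `blq`; flagged rows are treated as missing).
#' @param dose data.frame with `subject_id`, `dose_mg`.
#' @return data.frame with the [run_nca()] metrics per subject.
#' @export
nca_cohort <- function(conc, dose) {
  need_c <- c("subject_id", "time_h", "conc_ng_ml")
  if (!all(need_c %in% names(conc))) {
    stop("conc must have columns ", paste(need_c, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("subject_id", "dose_mg") %in% names(dose))) {
    stop("dose must have columns subject_id, dose_mg", call. = FALSE)
  }
  missing_dose <- setdiff(unique(conc$subject_id), dose$subject_id)
  if (length(missing_dose)) {
    stop("no dose for subject(s): ", paste(missing_dose, collapse = ", "),
         call. = FALSE)
  }
  cvals <- conc$conc_ng_ml
  if ("blq" %in% names(conc)) cvals[conc$blq %in% TRUE] <- NA_real_
  rows <- lapply(unique(conc$subject_id), function(id) {
    sel <- conc$subject_id == id
    o <- order(conc$time_h[sel])
    p <- conc_profile(id, conc$time_h[sel][o], cvals[sel][o],
                      dose$dose_mg[match(id, dose$subject_id)])
    as.data.frame(unclass(run_nca(p)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Geometric summary of a positive sample
#'
#' Geometric mean `exp(mean(log v))`, geometric SD `exp(sd(log v))` (sample
#' denominator; defined as 1 for a single value) and geometric coefficient
#' of variation `100 * sqrt(exp(s^2) - 1)` with `s = sd(log v)` — the
#' relative dispersion of a log-normal sample.
#'
#' @param values positive numeric vector, `n >= 1`.
#' @return list with `gm`, `gsd`, `cv_pct`, `n`.
#' @export
geo_summary <- function(values) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) < 1L) stop("need at least one value", call. = FALSE)
  if (any(values <= 0)) {
    stop("geometric summaries require strictly positive values",
         call. = FALSE)
  }
  lv <- log(values)
  s <- if (length(lv) > 1L) stats::sd(lv) else 0
  list(gm = exp(mean(lv)),
       gsd = exp(s),
       cv_pct = 100 * sqrt(exp(s^2) - 1),
       n = length(values))
}
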