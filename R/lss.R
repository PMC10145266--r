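#' Single-point regression of AUC on a timed concentration
#'
#' Ordinary least-squares fit `AUC = intercept + slope * C_t` for one
#' sampling time, with the coefficient of determination.
#'
#' @param conc_at_t concentrations at the sampling time, ng/mL.
#' @param auc_obs observed dosing-interval AUCs, ng.h/mL; same length.
#' @return list with `slope`, `intercept`, `r2`, `n`.
#' @export
fit_single_point <- function(conc_at_t, auc_obs) {
  x <- as.numeric(conc_at_t)
  y <- as.numeric(auc_obs)
  if (length(x) != length(y)) {
    stop("conc_at_t and auc_obs must have equal length", call. = FALSE)
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) {
    stop("need at least 3 paired observations", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("degenerate fit: predictor has zero variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = 1 - sse / sst,
       n = length(x))
}

#' Sheiner-Beal predictive performance of AUC predictions
#'
#' Per-subject relative prediction error
#' `PE_i = 100 * (AUC_pred,i - AUC_obs,i) / AUC_obs,i` (percent), summarised
#' as the mean prediction error (MPE), mean absolute prediction error (MAE),
#' the median and range of the signed and absolute errors, and for each
#' threshold `k` the count of subjects exceeding `|PE| > k` and the
#' percentage within, `F_k = 100 * (n - n_exceed_k) / n`. A `|PE|` exactly
#' equal to a threshold counts as within it.
#'
#' @param auc_pred predicted AUCs.
#' @param auc_obs observed AUCs; all > 0, same length.
#' @param thresholds percent thresholds for the F statistics, default
#'   `c(15, 20, 25)`.
#' @return An object of class `lss_performance`: list with `n`, `pe`
#'   (per-subject %), `mpe_mean`, `mae_mean`, `mpe_median`, `mpe_range`,
#'   `mae_median`, `mae_range`, `n_exceed` (named counts), `f` (named
#'   percentages).
#' @export
predictive_performance <- function(auc_pred, auc_obs,
                                   thresholds = c(15, 20, 25)) {
  pred <- as.numeric(auc_pred)
  obs <- as.numeric(auc_obs)
  if (length(pred) != length(obs) || length(obs) < 1L) {
    stop("auc_pred and auc_obs must be non-empty and of equal length",
         call. = FALSE)
  }
  if (anyNA(pred) || anyNA(obs)) stop("missing AUC values", call. = FALSE)
  if (any(obs <= 0)) {
    stop("observed AUCs must be positive", call. = FALSE)
  }
  if (any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  pe <- 100 * (pred - obs) / obs
  ape <- abs(pe)
  n_exceed <- vapply(thresholds, function(k) sum(ape > k), integer(1))
  names(n_exceed) <- paste0("gt", thresholds)
  f <- 100 * (length(pe) - n_exceed) / length(pe)
  names(f) <- paste0("f", thresholds)
  structure(list(
    n = length(pe),
    pe = pe,
    mpe_mean = mean(pe),
    mae_mean = mean(ape),
    mpe_median = stats::median(pe),
    mpe_range = range(pe),
    mae_median = stats::median(ape),
    mae_range = range(ape),
    n_exceed = n_exceed,
    f = f,
    thresholds = thresholds
  ), class = "lss_performance")
}

#' @export
print.lss_performance <- function(x, ...) {
  cat(sprintf("Predictive performance (n = %d): MPE %.1f%%, MAE %.1f%%\n",
              x$n, x$mpe_mean, x$mae_mean))
  cat("  F:", paste(sprintf("%s = %.0f%%", names(x$f), x$f), collapse = ", "),
      "\n")
  invisible(x)
}

#' Clinical acceptability of a limited-sampling equation
#'
#' A single-point equation is judged clinically acceptable when
#' `|MPE| <= 15`, `MAE <= 30`, `F15 > 40`, `F20 > 45` and `F25 > 50`
#' (all in percent). The MPE bound applies to the mean signed error.
#'
#' @param perf an `lss_performance` object (thresholds 15/20/25).
#' @param bounds named numeric vector `c(mpe, mae, f15, f20, f25)`.
#' @return logical verdict.
#' @export
lss_acceptable <- function(perf,
                           bounds = c(mpe = 15, mae = 30,
                                      f15 = 40, f20 = 45, f25 = 50)) {
  if (!inherits(perf, "lss_performance")) {
    stop("perf must be an lss_performance object", call. = FALSE)
  }
  if (length(perf$f) < 3L) {
    stop("acceptability needs the three F thresholds", call. = FALSE)
  }
  abs(perf$mpe_mean) <= bounds[["mpe"]] &&
    perf$mae_mean <= bounds[["mae"]] &&
    perf$f[[1]] > bounds[["f15"]] &&
    perf$f[[2]] > bounds[["f20"]] &&
    perf$f[[3]] > bounds[["f25"]]
}

#' Limited-sampling-strategy scan over the sampling schedule
#'
#' For every sampling time shared by the cohort this fits the single-point
#' regression of observed AUC0-12h on the concentration at that time,
#' computes in-sample AUC predictions (or leave-one-out predictions when
#' `loo = TRUE`), the Sheiner-Beal predictive-performance metrics and the
#' clinical acceptability verdict, plus the geometric summary of the
#' concentrations at that time. Subjects missing (BLQ) at a given time are
#' excluded from that time's row and counted in `n_excluded`.
#'
#' @param conc long concentration data.frame (`subject_id`, `time_h`,
#'   `conc_ng_ml`, optional `blq`).
#' @param nca per-subject NCA table from [nca_cohort()] (needs
#'   `subject_id`, `auc_0_12`).
#' @param thresholds F-statistic thresholds, percent.
#' @param bounds acceptability bounds, see [lss_acceptable()].
#' @param loo use leave-one-out predictions instead of in-sample ones.
#' @return An object of class `lss_scan`: list with `table` (one row per
#'   sampling time: `time_h`, `n`, `n_excluded`, `gm`, `gsd`, `slope`,
#'   `intercept`, `r2`, `mpe_mean`, `mae_mean`, `mpe_median`, `mpe_min`,
#'   `mpe_max`, `mae_median`, `mae_min`, `mae_max`, exceed counts, F
#'   percentages and `acceptable`) and `detail` (per-time performance
#'   objects and fitted values).
#' @export
lss_scan <- function(conc, nca, thresholds = c(15, 20, 25),
                     bounds = c(mpe = 15, mae = 30,
                                f15 = 40, f20 = 45, f25 = 50),
                     loo = FALSE) {
  need <- c("subject_id", "time_h", "conc_ng_ml")
  if (!all(need %in% names(conc))) {
    stop("conc must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("subject_id", "auc_0_12") %in% names(nca))) {
    stop("nca must have columns subject_id, auc_0_12", call. = FALSE)
  }
  cvals <- conc$conc_ng_ml
  if ("blq" %in% names(conc)) cvals[conc$blq %in% TRUE] <- NA_real_
  times <- sort(unique(conc$time_h))
  if (length(unique(nca$subject_id)) < 3L) {
    stop("need at least 3 subjects", call. = FALSE)
  }

  rows <- vector("list", length(times))
  detail <- vector("list", length(times))
  names(detail) <- as.character(times)
  for (i in seq_along(times)) {
    t0 <- times[i]
    sel <- conc$time_h == t0
    ids <- conc$subject_id[sel]
    x <- cvals[sel][match(nca$subject_id, ids)]
    y <- nca$auc_0_12
    keep <- !is.na(x) & x > 0
    n_excluded <- sum(!keep)
    x <- x[keep]; y <- y[keep]; ids_k <- nca$subject_id[keep]
    fit <- fit_single_point(x, y)
    pred <- if (loo) {
      vapply(seq_along(x), function(j) {
        fj <- fit_single_point(x[-j], y[-j])
        fj$intercept + fj$slope * x[j]
      }, numeric(1))
    } else {
      fit$intercept + fit$slope * x
    }
    perf <- predictive_performance(pred, y, thresholds)
    gs <- geo_summary(x)
    rows[[i]] <- data.frame(
      time_h = t0, n = length(x), n_excluded = n_excluded,
      gm = gs$gm, gsd = gs$gsd,
      slope = fit$slope, intercept = fit$intercept, r2 = fit$r2,
      mpe_mean = perf$mpe_mean, mae_mean = perf$mae_mean,
      mpe_median = perf$mpe_median,
      mpe_min = perf$mpe_range[1], mpe_max = perf$mpe_range[2],
      mae_median = perf$mae_median,
      mae_min = perf$mae_range[1], mae_max = perf$mae_range[2],
      stringsAsFactors = FALSE
    )
    for (j in seq_along(thresholds)) {
      rows[[i]][[paste0("n_exceed_", thresholds[j])]] <- perf$n_exceed[[j]]
      rows[[i]][[paste0("f", thresholds[j])]] <- perf$f[[j]]
    }
    rows[[i]]$acceptable <- lss_acceptable(perf, bounds)
    detail[[i]] <- list(subject_id = ids_k, conc = x, auc_obs = y,
                        auc_pred = pred, performance = perf)
  }
  structure(list(table = do.call(rbind, rows), detail = detail,
                 thresholds = thresholds, bounds = bounds, loo = loo),
            class = "lss_scan")
}

#' @export
print.lss_scan <- function(x, ...) {
  tab <- x$table
  cat(sprintf("Single-point limited-sampling scan (%s predictions)\n",
              if (x$loo) "leave-one-out" else "in-sample"))
  show <- data.frame(
    time_h = tab$time_h, n = tab$n,
    r2 = round(tab$r2, 3),
    MPE = round(tab$mpe_mean, 1), MAE = round(tab$mae_mean, 1),
    F15 = round(tab[[paste0("f", x$thresholds[1])]]),
    F20 = round(tab[[paste0("f", x$thresholds[2])]]),
    F25 = round(tab[[paste0("f", x$thresholds[3])]]),
    acceptable = tab$acceptable
  )
  print(show, row.names = FALSE)
  invisible(x)
}

#' @export
summary.lss_scan <- function(object, ...) {
  tab <- object$table
  best <- tab$time_h[which.max(tab$r2)]
  cat(sprintf(
    "Best single sampling time: %g h (R2 = %.3f); %d of %d times acceptable\n",
    best, max(tab$r2), sum(tab$acceptable), nrow(tab)))
  print(object)
  invisible(object$table)
}

#' @export
coef.lss_scan <- function(object, ...) {
  out <- as.matrix(object$table[, c("intercept", "slope")])
  rownames(out) <- paste0("t", object$table$time_h, "h")
  out
}

#' Predict AUC0-12h from a single timed concentration
#'
#' @param object an [lss_scan()] fit.
#' @param time_h the sampling time whose equation to use (must be one of the
#'   scanned times; default the time with the highest R2).
#' @param conc concentration(s) at that time, ng/mL.
#' @param ... unused.
#' @return Predicted AUC0-12h, ng.h/mL.
#' @export
predict.lss_scan <- function(object, conc, time_h = NULL, ...) {
  tab <- object$table
  if (is.null(time_h)) time_h <- tab$time_h[which.max(tab$r2)]
  i <- match(time_h, tab$time_h)
  if (is.na(i)) {
    stop("time_h must be one of the scanned sampling times", call. = FALSE)
  }
  tab$intercept[i] + tab$slope[i] * as.numeric(conc)
}

#' @export
residuals.lss_scan <- function(object, ...) {
  lapply(object$detail, function(d) {
    stats::setNames(d$auc_obs - d$auc_pred, d$subject_id)
  })
}

#' @export
plot.lss_scan <- function(x, which = c("r2", "fit"), time_h = NULL, ...) {
  which <- match.arg(which)
  tab <- x$table
  if (which == "r2") {
    graphics::plot(tab$time_h, tab$r2, type = "b", pch = 16,
                   xlab = "Sampling time (h)",
                   ylab = expression(R^2), ylim = c(0, 1), ...)
  } else {
    if (is.null(time_h)) time_h <- tab$time_h[which.max(tab$r2)]
    d <- x$detail[[as.character(time_h)]]
    if (is.null(d)) stop("no scan at that time", call. = FALSE)
    graphics::plot(d$conc, d$auc_obs, pch = 16,
                   xlab = sprintf("Concentration at %g h (ng/mL)", time_h),
                   ylab = "Observed AUC0-12h (ng.h/mL)", ...)
    i <- match(time_h, tab$time_h)
    graphics::abline(tab$intercept[i], tab$slope[i])
  }
  invisible(x)
}
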