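#' Evaluate published covariate models of tacrolimus apparent clearance
#'
#' Three population-pharmacokinetic covariate formulas for tacrolimus CL/F
#' from the transplant literature, evaluated exactly as published:
#' \describe{
#'   \item{darley}{`CL/F = 14.4 / (HCT/45)` — haematocrit only.}
#'   \item{chen}{`CL/F = 3.7 * (WT/70)^0.75 * (VOZ/2.02)^-0.288 *
#'     (DD/0.75)^0.618 * (HCT/31.5)^-0.511` — weight, voriconazole trough,
#'     tacrolimus daily dose and haematocrit; when `voz` is not supplied it
#'     defaults to its reference value 2.02, making that factor 1.}
#'   \item{cai}{`CL/F = 13.1 * (WT/70)^0.75 * (HCT/30)^-0.868 *
#'     (DD/3)^0.616 * (POT/30)^0.0807`, multiplied by 1.3 for CYP3A5*1
#'     carriers and by 0.638 under voriconazole comedication.}
#' }
#' Each power-law factor equals 1 at its reference covariate value, so
#' evaluation at all references returns the base constant exactly.
#'
#' @param model one of `"darley"`, `"chen"`, `"cai"`.
#' @param wt body weight, kg.
#' @param hct haematocrit, percent.
#' @param dd tacrolimus daily dose, mg.
#' @param voz voriconazole trough concentration (reference units, 2.02 at
#'   the Chen reference); optional, Chen only.
#' @param pot postoperative time, days (Cai only).
#' @param cyp3a5_expresser logical: carrier of at least one CYP3A5*1 allele
#'   (Cai only).
#' @param voriconazole logical: voriconazole comedication (Cai only).
#' @return Apparent clearance CL/F, L/h.
#' @export
evaluate_published_clf <- function(model = c("darley", "chen", "cai"),
                                   wt = NULL, hct = NULL, dd = NULL,
                                   voz = NULL, pot = NULL,
                                   cyp3a5_expresser = FALSE,
                                   voriconazole = FALSE) {
  model <- match.arg(model)
  need <- switch(model,
                 darley = c("hct"),
                 chen = c("wt", "dd", "hct"),
                 cai = c("wt", "hct", "dd", "pot"))
  vals <- list(wt = wt, hct = hct, dd = dd, voz = voz, pot = pot)
  for (nm in need) {
    v <- vals[[nm]]
    if (is.null(v)) {
      stop("model '", model, "' requires covariate '", nm, "'",
           call. = FALSE)
    }
    if (length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("covariate '", nm, "' must be a positive scalar", call. = FALSE)
    }
  }
  switch(model,
    darley = 14.4 / (hct / 45),
    chen = {
      if (is.null(voz)) voz <- 2.02
      if (voz <= 0) stop("covariate 'voz' must be positive", call. = FALSE)
      3.7 * (wt / 70)^0.75 * (voz / 2.02)^-0.288 *
        (dd / 0.75)^0.618 * (hct / 31.5)^-0.511
    },
    cai = {
      13.1 * (wt / 70)^0.75 * (hct / 30)^-0.868 * (dd / 3)^0.616 *
        (pot / 30)^0.0807 *
        (if (isTRUE(cyp3a5_expresser)) 1.3 else 1) *
        (if (isTRUE(voriconazole)) 0.638 else 1)
    })
}

#' Cross-study comparison of adjusted apparent clearance
#'
#' Evaluates each published covariate model at one covariate profile and
#' tabulates the adjusted CL/F values next to the cohort's own
#' geometric-mean CL/F.
#'
#' @param own_clf cohort geometric-mean CL/F, L/h.
#' @param wt,hct,dd,pot,voz covariates, see [evaluate_published_clf()];
#'   defaults are the typical patient used for adjustment (64.5 kg,
#'   haematocrit 30 percent, daily dose 2 mg, postoperative day 3.5).
#' @param cyp3a5_expresser,voriconazole flags for the Cai model.
#' @return data.frame with `model`, `adjusted_clf` (L/h) and
#'   `ratio_to_cohort`; the last row is the cohort itself.
#' @export
comparison_table <- function(own_clf, wt = 64.5, hct = 30, dd = 2,
                             pot = 3.5, voz = NULL,
                             cyp3a5_expresser = FALSE, voriconazole = TRUE) {
  if (length(own_clf) != 1L || !is.finite(own_clf) || own_clf <= 0) {
    stop("own_clf must be a positive scalar", call. = FALSE)
  }
  clfs <- c(
    darley = evaluate_published_clf("darley", hct = hct),
    chen = evaluate_published_clf("chen", wt = wt, hct = hct, dd = dd,
                                  voz = voz),
    cai = evaluate_published_clf("cai", wt = wt, hct = hct, dd = dd,
                                 pot = pot,
                                 cyp3a5_expresser = cyp3a5_expresser,
                                 voriconazole = voriconazole),
    cohort = own_clf
  )
  data.frame(model = names(clfs),
             adjusted_clf = unname(clfs),
             ratio_to_cohort = unname(clfs) / own_clf,
             stringsAsFactors = FALSE)
}
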