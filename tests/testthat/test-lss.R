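test_that("single-point regression matches closed-form least squares", {
  # perfect proportionality
  f <- fit_single_point(c(2, 5, 9, 14), 10 * c(2, 5, 9, 14))
  expect_equal(f$slope, 10)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r2, 1)

  # hand-solved normal equations for (1,10), (2,20), (3,33)
  f2 <- fit_single_point(c(1, 2, 3), c(10, 20, 33))
  expect_equal(f2$slope, 11.5)
  expect_equal(f2$intercept, -2)

  # R2 equals the squared Pearson correlation
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(20); y <- 2 * x + rnorm(20)
    f3 <- fit_single_point(x, y)
    expect_equal(f3$r2, cor(x, y)^2, tolerance = 1e-12)
  }
  expect_error(fit_single_point(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(fit_single_point(1:2, 1:2), "at least 3")
})

test_that("prediction-error summaries follow the percent-error definition", {
  perf0 <- predictive_performance(c(100, 50, 80), c(100, 50, 80))
  expect_equal(perf0$mpe_mean, 0)
  expect_equal(perf0$mae_mean, 0)
  expect_equal(unname(perf0$f), c(100, 100, 100))
  expect_equal(unname(perf0$n_exceed), c(0L, 0L, 0L))

  # hand arithmetic: PE = (+10, -20)
  perf <- predictive_performance(c(110, 80), c(100, 100))
  expect_equal(perf$pe, c(10, -20))
  expect_equal(perf$mpe_mean, -5)
  expect_equal(perf$mae_mean, 15)
  expect_equal(unname(perf$f), c(50, 100, 100))
  expect_equal(perf$mpe_range, c(-20, 10))
  expect_equal(perf$mae_range, c(10, 20))

  # a |PE| exactly at a threshold counts as within it
  at15 <- predictive_performance(c(115, 100), c(100, 100))
  expect_equal(unname(at15$n_exceed), c(0L, 0L, 0L))
  expect_error(predictive_performance(c(1, 2), c(0, 2)), "positive")
})

test_that("F percentages are monotone and |MPE| never exceeds MAE", {
  set.seed(29)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    obs <- exp(rnorm(n, 5, 0.5))
    pred <- obs * exp(rnorm(n, 0, 0.3))
    perf <- predictive_performance(pred, obs)
    expect_true(all(diff(perf$f) >= 0))
    expect_true(all(diff(perf$n_exceed) <= 0))
    expect_lte(abs(perf$mpe_mean), perf$mae_mean)
    expect_equal(unname(100 * (perf$n - perf$n_exceed) / perf$n),
                 unname(perf$f))
  }
})

test_that("the clinical acceptability rule combines all five bounds", {
  mk <- function(pe) predictive_performance(100 * (1 + pe / 100),
                                            rep(100, length(pe)))
  expect_true(lss_acceptable(mk(rep(0, 5))))
  # single-criterion failures
  expect_false(lss_acceptable(mk(rep(16, 14))))           # MPE > 15
  mixed <- mk(c(rep(40, 7), rep(-40, 7)))                  # MPE 0, MAE 40
  expect_false(lss_acceptable(mixed))
  # F15 must be strictly above 40
  borderline <- mk(c(rep(0, 4), rep(20, 6)))               # F15 = 40 exactly
  expect_false(lss_acceptable(borderline))
})

test_that("the reported 4-h performance profile is judged acceptable", {
  # MPE -2%, MAE 7%, F15/F20/F25 = 79/93/100 with n = 14: construct a
  # per-subject error vector reproducing those summaries via the package
  pe <- c(-24, -16, 16, rep(-9, 5), rep(6, 5), -2)
  perf <- predictive_performance(100 * (1 + pe / 100), rep(100, 14))
  expect_equal(unname(perf$n_exceed), c(3L, 1L, 0L))
  expect_equal(round(unname(perf$f)), c(79, 93, 100))
  expect_true(abs(perf$mpe_mean) <= 15 && perf$mae_mean <= 30)
  expect_true(lss_acceptable(perf))
})

test_that("the scan reproduces a proportional relationship and is replication-invariant", {
  coh <- simulate_population(study_config(seed = 6))
  nca <- nca_cohort(coh$conc, coh$dose)
  # overwrite the 4-h samples to be exactly proportional to AUC
  conc <- coh$conc
  i4 <- conc$time_h == 4
  conc$conc_ng_ml[i4] <-
    nca$auc_0_12[match(conc$subject_id[i4], nca$subject_id)] / 10
  sc <- lss_scan(conc, nca)
  expect_equal(sc$table$r2[sc$table$time_h == 4], 1, tolerance = 1e-12)
  expect_true(all(sc$table$r2 <= 1 + 1e-12))
  expect_true(all(sc$table$r2 >= 0))

  # duplicating every subject changes nothing
  conc2 <- conc; conc2$subject_id <- paste0(conc2$subject_id, "_b")
  nca2 <- nca; nca2$subject_id <- paste0(nca2$subject_id, "_b")
  scd <- lss_scan(rbind(conc, conc2), rbind(nca, nca2))
  expect_equal(scd$table$slope, sc$table$slope)
  expect_equal(scd$table$intercept, sc$table$intercept)
  expect_equal(scd$table$r2, sc$table$r2)
  expect_equal(scd$table$f15, sc$table$f15)
})

test_that("mid-interval concentrations predict AUC better than the trough", {
  coh <- simulate_population(study_config(seed = 1))
  nca <- nca_cohort(coh$conc, coh$dose)
  tab <- lss_scan(coh$conc, nca)$table
  expect_gt(max(tab$r2[tab$time_h %in% c(4, 6)]),
            tab$r2[tab$time_h == 0])
})

test_that("R2 is invariant under affine predictor rescaling and residuals centre at zero", {
  coh <- simulate_population(study_config(seed = 15))
  nca <- nca_cohort(coh$conc, coh$dose)
  sc <- lss_scan(coh$conc, nca)
  conc2 <- coh$conc
  conc2$conc_ng_ml <- 3 * conc2$conc_ng_ml + 2
  sc2 <- lss_scan(conc2, nca)
  expect_equal(sc2$table$r2, sc$table$r2, tolerance = 1e-10)
  # in-sample OLS: mean signed residual is zero in AUC units
  for (r in residuals(sc)) expect_equal(mean(r), 0, tolerance = 1e-9)
  # but MPE (ratio-based) generally is not zero
  expect_false(all(abs(sc$table$mpe_mean) < 1e-9))
})

test_that("subjects missing a timepoint are excluded from that row only", {
  coh <- simulate_population(study_config(seed = 21))
  nca <- nca_cohort(coh$conc, coh$dose)
  conc <- coh$conc
  drop <- conc$time_h == 6 & conc$subject_id %in% c("S001", "S002")
  conc$conc_ng_ml[drop] <- NA
  sc <- lss_scan(conc, nca)
  row6 <- sc$table[sc$table$time_h == 6, ]
  expect_equal(row6$n, 12)
  expect_equal(row6$n_excluded, 2)
  expect_equal(sc$table$n[sc$table$time_h == 4], 14)
})

test_that("scan methods expose coefficients, predictions and plots", {
  coh <- simulate_population(study_config(seed = 2))
  nca <- nca_cohort(coh$conc, coh$dose)
  sc <- lss_scan(coh$conc, nca)
  cf <- coef(sc)
  expect_equal(dim(cf), c(9L, 2L))
  # predict() applies the chosen row's equation
  i <- match(4, sc$table$time_h)
  expect_equal(predict(sc, conc = 10, time_h = 4),
               sc$table$intercept[i] + 10 * sc$table$slope[i])
  expect_error(predict(sc, conc = 10, time_h = 3), "scanned")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(sc))
  expect_invisible(plot(sc, which = "fit"))
  expect_output(print(summary(sc)), "Best single sampling time")
})

test_that("leave-one-out predictions differ from in-sample ones but keep the contracts", {
  coh <- simulate_population(study_config(seed = 33))
  nca <- nca_cohort(coh$conc, coh$dose)
  in_s <- lss_scan(coh$conc, nca, loo = FALSE)
  loo <- lss_scan(coh$conc, nca, loo = TRUE)
  expect_equal(loo$table$r2, in_s$table$r2)    # fit itself unchanged
  expect_false(isTRUE(all.equal(loo$table$mae_mean, in_s$table$mae_mean)))
  expect_true(all(loo$table$mae_mean >= in_s$table$mae_mean - 1e-9))
})
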