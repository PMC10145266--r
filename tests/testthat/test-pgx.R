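test_that("carrier classification follows the binary sub-grouping", {
  g <- data.frame(
    cyp3a5 = c("*1/*1", "*1/*3", "*3/*3"),
    cyp3a4 = c("*1G/*1G", "*1/*1G", "*1/*1"),
    stringsAsFactors = FALSE
  )
  cl <- classify_carriers(g)
  expect_equal(cl$cyp3a5_class,
               c("non-CYP3A5*3/*3", "non-CYP3A5*3/*3", "CYP3A5*3/*3"))
  expect_equal(cl$cyp3a4_class,
               c("non-CYP3A4*1/*1", "non-CYP3A4*1/*1", "CYP3A4*1/*1"))
  expect_error(classify_carriers(data.frame(cyp3a5 = "*2/*2",
                                            cyp3a4 = "*1/*1")),
               "unknown genotype")
})

test_that("Hardy-Weinberg testing matches hand computation on the study counts", {
  # perfect HWE proportions
  h0 <- hwe_test(c(25, 50, 25))
  expect_equal(h0$chi2, 0)
  expect_equal(h0$p_chisq, 1)

  # CYP3A5 counts (1, 8, 5): expecteds (1.79, 6.43, 5.79) from p = 10/28
  h <- hwe_test(c(1, 8, 5))
  expect_equal(h$allele_freq, 10 / 28)
  expect_equal(h$expected, 14 * c((10 / 28)^2, 2 * (10 / 28) * (18 / 28),
                                  (18 / 28)^2), tolerance = 1e-12)
  expect_equal(h$chi2, 0.836, tolerance = 1e-3)
  expect_equal(h$p_chisq, 0.360, tolerance = 1e-2)
  expect_gt(h$p, 0.05)
  expect_identical(h$method, "exact")   # smallest expected cell < 5
  expect_equal(sum(h$expected), sum(h$observed))

  # maximal disequilibrium: no heterozygotes at intermediate frequency
  h2 <- hwe_test(c(10, 0, 10))
  expect_lt(h2$p_exact, 0.01)

  # monomorphic convention
  hm <- hwe_test(c(14, 0, 0))
  expect_equal(hm$p, 1)
  expect_identical(hm$method, "monomorphic")
  expect_error(hwe_test(c(-1, 2, 3)), "non-negative")
})

test_that("exact test agrees with an enumeration oracle", {
  # independent enumeration: probability of each heterozygote count
  # conditional on allele counts, summed over outcomes at most as probable
  oracle <- function(obs) {
    n <- sum(obs); na <- 2 * obs[1] + obs[2]; nb <- 2 * n - na
    hets <- seq(na %% 2, min(na, nb), by = 2)
    pr <- sapply(hets, function(h) {
      exp(h * log(2) + lfactorial(n) + lfactorial(na) + lfactorial(nb) -
            lfactorial((na - h) / 2) - lfactorial(h) -
            lfactorial((nb - h) / 2) - lfactorial(2 * n))
    })
    pr <- pr / sum(pr)
    sum(pr[pr <= pr[match(obs[2], hets)] * (1 + 1e-12)])
  }
  for (obs in list(c(1, 8, 5), c(10, 0, 10), c(3, 3, 3), c(0, 2, 12))) {
    expect_equal(hwe_test(obs)$p_exact, oracle(obs), tolerance = 1e-10)
  }
})

test_that("chi-squared and exact tests track each other for well-filled tables", {
  # the two-sided probability-ordering exact p differs from the asymptotic
  # tail by up to ~0.1 on a discrete support even with expected counts
  # >= 10, so agreement is asserted on the typical gap and on the
  # significance verdict, not pointwise
  set.seed(19)
  gap <- c(); verdict_same <- c()
  for (i in 1:100) {
    p <- runif(1, 0.3, 0.7)
    g <- sample(0:2, 200, replace = TRUE,
                prob = c(p^2, 2 * p * (1 - p), (1 - p)^2))
    h <- hwe_test(c(sum(g == 0), sum(g == 1), sum(g == 2)))
    if (all(h$expected >= 10)) {
      gap <- c(gap, abs(h$p_chisq - h$p_exact))
      verdict_same <- c(verdict_same, (h$p_chisq < 0.05) == (h$p_exact < 0.05))
    }
  }
  expect_lt(median(gap), 0.05)
  expect_gte(mean(verdict_same), 0.95)
})

test_that("EM haplotype estimation equals direct counting without double heterozygotes", {
  g <- data.frame(
    cyp3a5 = c("*1/*1", "*1/*1", "*1/*3", "*3/*3", "*3/*3", "*1/*3"),
    cyp3a4 = c("*1G/*1G", "*1/*1G", "*1/*1", "*1/*1", "*1/*1", "*1/*1"),
    stringsAsFactors = FALSE
  )
  # phases are unambiguous; haplotype counts can be read off directly:
  # A5*1-A4*1G: 2 + 1 = 3; A5*1-A4*1: 1 + 1 + 1 = 3; A5*3-A4*1: 6
  ld <- em_haplotypes(g)
  expect_equal(unname(ld$hap_freqs), c(3, 3, 0, 6) / 12, tolerance = 1e-8)

  # concordant double homozygotes: complete LD
  g2 <- data.frame(cyp3a5 = rep(c("*1/*1", "*3/*3"), each = 4),
                   cyp3a4 = rep(c("*1G/*1G", "*1/*1"), each = 4),
                   stringsAsFactors = FALSE)
  ld2 <- em_haplotypes(g2)
  expect_equal(unname(ld2$hap_freqs), c(0.5, 0, 0, 0.5), tolerance = 1e-8)
  expect_equal(ld2$d_prime, 1)
  expect_equal(ld2$r2, 1)
})

test_that("EM recovers known haplotype frequencies and increases the likelihood", {
  truth <- c(0.4, 0.3, 0.2, 0.1)
  g <- simulate_genotypes(1e4, truth, seed = 27)
  ld <- em_haplotypes(g)
  expect_true(ld$ok)
  expect_true(all(abs(ld$hap_freqs - truth) < 0.02))
  expect_true(all(diff(ld$loglik_trace) > -1e-9))

  # D' = 1 whenever a haplotype class is absent (both loci polymorphic)
  g3 <- simulate_genotypes(500, c(6, 4, 0, 18) / 28, seed = 3)
  ld3 <- em_haplotypes(g3)
  expect_equal(ld3$d_prime, 1, tolerance = 1e-6)

  # monomorphic locus: flagged, no numbers
  gm <- data.frame(cyp3a5 = rep("*3/*3", 5),
                   cyp3a4 = c("*1/*1", "*1/*1G", "*1/*1", "*1/*1", "*1/*1"),
                   stringsAsFactors = FALSE)
  ldm <- em_haplotypes(gm)
  expect_false(ldm$ok)
  expect_true(is.na(ldm$d_prime) && is.na(ldm$r2))
})

test_that("log-scale ANOVA behaves like the pooled t-test and is scale-invariant", {
  set.seed(37)
  x <- exp(rnorm(9, log(18), 0.5))
  y <- exp(rnorm(5, log(3.4), 0.45))
  v <- c(x, y)
  g <- rep(c("expresser", "nonexpresser"), c(9, 5))
  cmp <- compare_groups(v, g)
  tt <- t.test(log(x), log(y), var.equal = TRUE)
  expect_equal(cmp$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(cmp$p, tt$p.value, tolerance = 1e-10)

  cmp2 <- compare_groups(v * 7.3, g)
  expect_equal(cmp2$f, cmp$f, tolerance = 1e-9)

  same <- compare_groups(rep(c(2, 2, 3, 3), 2),
                         rep(c("a", "b"), each = 4))
  expect_equal(same$f, 0, tolerance = 1e-12)

  expect_error(compare_groups(1:5, c("a", "a", "a", "a", "b")),
               "fewer than 2 members.*b")
  expect_error(compare_groups(c(-1, 2, 3, 4), rep(c("a", "b"), 2)),
               "positive")
})

test_that("five-fold clearance separation is detected at the study scale", {
  coh <- simulate_population(study_config(seed = 10))
  nca <- nca_cohort(coh$conc, coh$dose)
  cls <- classify_carriers(coh$genotypes)
  g <- cls$cyp3a5_class[match(nca$subject_id, cls$subject_id)]
  expect_lt(compare_groups(nca$clf, g)$p, 0.001)
})

test_that("Spearman correlation scan handles perfect, inverse and degenerate covariates", {
  set.seed(43)
  y <- exp(rnorm(14, 2, 0.5))
  cov <- data.frame(same = y, inv = exp(-y), flat = rep(1.7, 14),
                    noise = rnorm(14))
  out <- spearman_scan(cov, y)
  expect_equal(out$rho[out$covariate == "same"], 1)
  expect_equal(out$rho[out$covariate == "inv"], -1)
  expect_identical(out$flag[out$covariate == "flat"], "constant")
  expect_true(is.na(out$rho[out$covariate == "flat"]))
  expect_error(spearman_scan(cov[1:2, ], y[1:2]), "fewer than 3")
})

test_that("the Spearman p-value holds its nominal size under permutation", {
  set.seed(53)
  y <- rnorm(20)
  x <- rnorm(20)
  hits <- 0L
  reps <- 2000L
  for (i in seq_len(reps)) {
    out <- spearman_scan(data.frame(x = sample(x)), y)
    if (out$p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / reps, 0.035)
  expect_lt(hits / reps, 0.065)
})
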