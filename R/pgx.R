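.cyp3a5_levels <- c("*1/*1", "*1/*3", "*3/*3")
.cyp3a4_levels <- c("*1/*1", "*1/*1G", "*1G/*1G")

#' Carrier classification of CYP3A genotypes
#'
#' Sub-classifies each subject into the binary groups used for
#' genotype-stratified comparisons: CYP3A5 `*3/*3` carriers (non-expressers)
#' versus all other CYP3A5 genotypes, and CYP3A4 `*1/*1` carriers versus
#' carriers of at least one `*1G` allele.
#'
#' @param genotypes data.frame with columns `cyp3a5` (one of `*1/*1`,
#'   `*1/*3`, `*3/*3`) and `cyp3a4` (one of `*1/*1`, `*1/*1G`, `*1G/*1G`).
#' @return The input with added character columns `cyp3a5_class`
#'   (`"CYP3A5*3/*3"` / `"non-CYP3A5*3/*3"`) and `cyp3a4_class`
#'   (`"CYP3A4*1/*1"` / `"non-CYP3A4*1/*1"`).
#' @export
classify_carriers <- function(genotypes) {
  if (!all(c("cyp3a5", "cyp3a4") %in% names(genotypes))) {
    stop("genotypes must have columns cyp3a5 and cyp3a4", call. = FALSE)
  }
  bad5 <- setdiff(unique(genotypes$cyp3a5), .cyp3a5_levels)
  bad4 <- setdiff(unique(genotypes$cyp3a4), .cyp3a4_levels)
  if (length(bad5) || length(bad4)) {
    stop("unknown genotype string(s): ",
         paste(c(bad5, bad4), collapse = ", "), call. = FALSE)
  }
  genotypes$cyp3a5_class <- ifelse(genotypes$cyp3a5 == "*3/*3",
                                   "CYP3A5*3/*3", "non-CYP3A5*3/*3")
  genotypes$cyp3a4_class <- ifelse(genotypes$cyp3a4 == "*1/*1",
                                   "CYP3A4*1/*1", "non-CYP3A4*1/*1")
  genotypes
}

# Levene-Haldane distribution of the heterozygote count conditional on the
# allele counts; used for the exact Hardy-Weinberg test.
.hwe_exact_p <- function(n_aa_obs, n_het_obs, n_bb_obs) {
  n <- n_aa_obs + n_het_obs + n_bb_obs
  n_a <- 2 * n_aa_obs + n_het_obs
  n_b <- 2 * n - n_a
  hets <- seq(n_a %% 2, min(n_a, n_b), by = 2)
  logp <- vapply(hets, function(h) {
    naa <- (n_a - h) / 2
    nbb <- (n_b - h) / 2
    h * log(2) + lfactorial(n) - lfactorial(naa) - lfactorial(h) -
      lfactorial(nbb) + lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het_obs, hets)]
  sum(p[p <= obs * (1 + 1e-12)])
}

#' Hardy-Weinberg equilibrium test for one biallelic locus
#'
#' From the genotype counts `(n_AA, n_Aa, n_aa)` the allele frequency is
#' estimated and the expected counts `n * (p^2, 2pq, q^2)` computed. The
#' chi-squared statistic (1 df) is always reported; the p-value used for the
#' verdict comes from the exact test (full enumeration of heterozygote
#' counts conditional on the allele counts) whenever any expected count is
#' below 5, from the chi-squared approximation otherwise. A monomorphic
#' sample returns `p = 1` by convention.
#'
#' @param counts integer vector `(n_AA, n_Aa, n_aa)`.
#' @return An object of class `hwe_result`: list with `observed`,
#'   `expected`, `allele_freq` (of A), `chi2`, `df`, `p`, `p_chisq`,
#'   `p_exact`, `method`.
#' @export
hwe_test <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L || any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be 3 non-negative genotype counts (AA, Aa, aa)",
         call. = FALSE)
  }
  n <- sum(counts)
  if (n < 1) stop("need at least one subject", call. = FALSE)
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  q <- 1 - p
  expected <- n * c(p^2, 2 * p * q, q^2)

  if (p == 0 || p == 1) {
    res <- list(observed = counts, expected = expected, allele_freq = p,
                chi2 = 0, df = 1L, p = 1, p_chisq = 1, p_exact = 1,
                method = "monomorphic")
    class(res) <- "hwe_result"
    return(res)
  }
  chi2 <- sum((counts - expected)^2 / expected)
  p_chisq <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  p_exact <- .hwe_exact_p(counts[1], counts[2], counts[3])
  method <- if (any(expected < 5)) "exact" else "chi-squared"
  res <- list(observed = counts, expected = expected, allele_freq = p,
              chi2 = chi2, df = 1L,
              p = if (method == "exact") p_exact else p_chisq,
              p_chisq = p_chisq, p_exact = p_exact, method = method)
  class(res) <- "hwe_result"
  res
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf(
    "Hardy-Weinberg test (%s): chi2 = %.3f (df 1), p = %.4g\n",
    x$method, x$chi2, x$p))
  cat(sprintf("  observed %s, expected %s\n",
              paste(x$observed, collapse = "/"),
              paste(round(x$expected, 2), collapse = "/")))
  invisible(x)
}

#' EM haplotype-frequency and linkage-disequilibrium estimation
#'
#' Maximum-likelihood haplotype frequencies for the two-locus system
#' CYP3A5*3 x CYP3A4*1G from unphased genotypes. Only double heterozygotes
#' are phase-ambiguous; the EM algorithm splits them between the cis
#' (`*1`-`*1G` / `*3`-`*1`) and trans configurations according to the
#' current frequency estimates and re-normalises until the largest frequency
#' change is below `tol`. Disequilibrium summaries follow:
#' `D = f(*1,*1G) - p(*1) p(*1G)`, `D' = |D| / Dmax`, and
#' `r2 = D^2 / (p(*1) p(*3) p(*1G) p(*1))`.
#'
#' @param genotypes data.frame with `cyp3a5`, `cyp3a4` genotype strings.
#' @param tol convergence tolerance on haplotype frequencies.
#' @param max_iter iteration cap.
#' @return An object of class `ld_result`: list with `hap_freqs` (named,
#'   order A5*1-A4*1G, A5*1-A4*1, A5*3-A4*1G, A5*3-A4*1), allele
#'   frequencies, `D`, `d_prime`, `r2`, `em_iterations`, `loglik`,
#'   `loglik_trace`, and `ok = FALSE` with `NA` summaries when a locus is
#'   monomorphic.
#' @export
em_haplotypes <- function(genotypes, tol = 1e-8, max_iter = 1000L) {
  if (!all(c("cyp3a5", "cyp3a4") %in% names(genotypes))) {
    stop("genotypes must have columns cyp3a5 and cyp3a4", call. = FALSE)
  }
  if (nrow(genotypes) < 2L) stop("need at least 2 subjects", call. = FALSE)
  g5 <- match(genotypes$cyp3a5, .cyp3a5_levels)
  g4 <- match(genotypes$cyp3a4, .cyp3a4_levels)
  if (anyNA(g5) || anyNA(g4)) {
    stop("unknown genotype string(s)", call. = FALSE)
  }
  a_copies <- c(2L, 1L, 0L)[g5]   # CYP3A5*1 copies
  b_copies <- c(0L, 1L, 2L)[g4]   # CYP3A4*1G copies
  n <- length(a_copies)

  hap_names <- c("A5*1-A4*1G", "A5*1-A4*1", "A5*3-A4*1G", "A5*3-A4*1")
  p_a <- sum(a_copies) / (2 * n)
  p_b <- sum(b_copies) / (2 * n)
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    res <- list(hap_freqs = stats::setNames(rep(NA_real_, 4), hap_names),
                p_cyp3a5_1 = p_a, p_cyp3a4_1g = p_b,
                D = NA_real_, d_prime = NA_real_, r2 = NA_real_,
                em_iterations = 0L, loglik = NA_real_,
                loglik_trace = numeric(0), ok = FALSE)
    class(res) <- "ld_result"
    return(res)
  }

  # cell counts over the 3x3 genotype table, indexed by (A copies, B copies)
  cell <- table(factor(a_copies, levels = 0:2),
                factor(b_copies, levels = 0:2))

  # haplotype composition (AB, Ab, aB, ab counts per subject) of each
  # unambiguous genotype cell, keyed "a.b"; the (1,1) cell is ambiguous
  fixed_tab <- list(
    "0.0" = c(0, 0, 0, 2), "0.1" = c(0, 0, 1, 1), "0.2" = c(0, 0, 2, 0),
    "1.0" = c(0, 1, 0, 1), "1.2" = c(1, 0, 1, 0),
    "2.0" = c(0, 2, 0, 0), "2.1" = c(1, 1, 0, 0), "2.2" = c(2, 0, 0, 0)
  )
  fixed_contrib <- function(a, b) fixed_tab[[paste(a, b, sep = ".")]]

  f <- rep(0.25, 4)
  n_dh <- cell["1", "1"]
  trace <- numeric(0)
  loglik <- function(f) {
    ll <- 0
    for (a in 0:2) for (b in 0:2) {
      m <- cell[as.character(a), as.character(b)]
      if (m == 0) next
      if (a == 1 && b == 1) {
        pr <- 2 * f[1] * f[4] + 2 * f[2] * f[3]
      } else {
        idx <- rep(1:4, fixed_contrib(a, b))
        pr <- if (idx[1] == idx[2]) f[idx[1]]^2 else 2 * f[idx[1]] * f[idx[2]]
      }
      ll <- ll + m * log(pr)
    }
    ll
  }

  it <- 0L
  repeat {
    it <- it + 1L
    hap_counts <- numeric(4)
    for (a in 0:2) for (b in 0:2) {
      m <- cell[as.character(a), as.character(b)]
      if (m == 0 || (a == 1 && b == 1)) next
      hap_counts <- hap_counts + m * fixed_contrib(a, b)
    }
    if (n_dh > 0) {
      cis <- f[1] * f[4]
      trans <- f[2] * f[3]
      w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
      hap_counts <- hap_counts + n_dh * (w * c(1, 0, 0, 1) +
                                           (1 - w) * c(0, 1, 1, 0))
    }
    f_new <- hap_counts / (2 * n)
    trace <- c(trace, loglik(f_new))
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol || it >= max_iter) break
  }

  p_A <- f[1] + f[2]   # CYP3A5*1
  p_B <- f[1] + f[3]   # CYP3A4*1G
  D <- f[1] - p_A * p_B
  d_max <- if (D >= 0) min(p_A * (1 - p_B), (1 - p_A) * p_B)
  else min(p_A * p_B, (1 - p_A) * (1 - p_B))
  d_prime <- if (d_max > 0) abs(D) / d_max else 0
  r2 <- D^2 / (p_A * (1 - p_A) * p_B * (1 - p_B))
  res <- list(hap_freqs = stats::setNames(f, hap_names),
              p_cyp3a5_1 = p_A, p_cyp3a4_1g = p_B,
              D = D, d_prime = d_prime, r2 = r2,
              em_iterations = it, loglik = trace[length(trace)],
              loglik_trace = trace, ok = TRUE)
  class(res) <- "ld_result"
  res
}

#' @export
print.ld_result <- function(x, ...) {
  if (!x$ok) {
    cat("Linkage disequilibrium: undefined (monomorphic locus)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Two-locus LD (EM, %d iterations): D' = %.3f, r2 = %.3f\n",
    x$em_iterations, x$d_prime, x$r2))
  cat("  haplotype frequencies:",
      paste(sprintf("%s %.3f", names(x$hap_freqs), x$hap_freqs),
            collapse = ", "), "\n")
  invisible(x)
}

#' Genotype-group comparison of a log-scale pharmacokinetic parameter
#'
#' One-way analysis of variance on the natural-log-transformed parameter,
#' the standard comparison for log-normally distributed exposure metrics.
#'
#' @param values positive numeric vector.
#' @param groups group labels; every group must have at least 2 members and
#'   there must be at least 2 groups.
#' @return list with `f` (F statistic), `p`, `df` (numerator, denominator).
#' @export
compare_groups <- function(values, groups) {
  values <- as.numeric(values)
  g <- factor(groups)
  if (length(values) != length(g)) {
    stop("values and groups must have equal length", call. = FALSE)
  }
  if (any(is.na(values)) || any(values <= 0)) {
    stop("values must be positive (log scale comparison)", call. = FALSE)
  }
  g <- droplevels(g)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    stop("group(s) with fewer than 2 members: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  a <- stats::anova(stats::lm(log(values) ~ g))
  list(f = a[["F value"]][1], p = a[["Pr(>F)"]][1],
       df = c(a$Df[1], a$Df[2]))
}

#' Spearman correlation scan of clinical covariates
#'
#' Rank correlation (mid-ranks for ties, two-sided asymptotic p) between
#' each continuous covariate and one pharmacokinetic parameter.
#'
#' @param covariates data.frame of numeric covariates (one column each).
#' @param parameter numeric vector, one value per row of `covariates`.
#' @return data.frame with `covariate`, `n`, `rho`, `p`, `flag`
#'   (`"constant"` when a covariate has no variation and rho is undefined).
#' @export
spearman_scan <- function(covariates, parameter) {
  if (!is.data.frame(covariates)) {
    stop("covariates must be a data.frame", call. = FALSE)
  }
  y <- as.numeric(parameter)
  if (nrow(covariates) != length(y)) {
    stop("parameter must have one value per covariate row", call. = FALSE)
  }
  rows <- lapply(names(covariates), function(nm) {
    x <- as.numeric(covariates[[nm]])
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) < 3L) {
      stop("covariate '", nm, "' has fewer than 3 paired values",
           call. = FALSE)
    }
    if (stats::var(x[keep]) == 0) {
      return(data.frame(covariate = nm, n = sum(keep), rho = NA_real_,
                        p = NA_real_, flag = "constant",
                        stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(
      stats::cor.test(x[keep], y[keep], method = "spearman",
                      exact = FALSE, alternative = "two.sided"))
    data.frame(covariate = nm, n = sum(keep),
               rho = unname(ct$estimate), p = ct$p.value, flag = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
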