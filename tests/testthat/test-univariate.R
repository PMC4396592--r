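test_that("fit_univariate matches the normal-equations oracle", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(8:50, 1)
    e <- rnorm(n); m <- rnorm(n)
    y <- 0.5 - 0.8 * m + 1.1 * e + rnorm(n, sd = 0.4)
    f <- fit_univariate(y, e, m)
    o <- oracle_ols(y, cbind(1, m, e))
    expect_equal(c(f$alpha, f$beta, f$gamma), o$coef, tolerance = 1e-10)
    expect_equal(f$p_beta, o$p[2], tolerance = 1e-10)
    expect_equal(f$p_gamma, o$p[3], tolerance = 1e-10)
  }
})

test_that("exact and null designs behave as the model dictates", {
  set.seed(12)
  n <- 40
  e <- rnorm(n); m <- rnorm(n)
  # noise-free data from alpha = 0, beta = -1, gamma = 1
  f <- fit_univariate(-m + e, e, m)
  expect_equal(f$alpha, 0, tolerance = 1e-8)
  expect_equal(f$beta, -1, tolerance = 1e-8)
  expect_equal(f$gamma, 1, tolerance = 1e-8)

  # logP = logE exactly, logM pure noise
  f2 <- fit_univariate(e, e, m)
  expect_equal(f2$gamma, 1, tolerance = 1e-8)
  expect_equal(f2$beta, 0, tolerance = 1e-8)
})

test_that("degenerate designs are flagged, not fatal", {
  set.seed(13)
  e <- rnorm(20)
  f <- fit_univariate(rnorm(20), e, 2 * e)  # logM proportional to logE
  expect_true(f$degenerate)
  expect_equal(f$p_beta, 1)
  expect_warning(f2 <- fit_univariate(rnorm(3), rnorm(3), rnorm(3)),
                 "usable samples")
  expect_true(f2$degenerate)
})

test_that("missing values are excluded pairwise from a single fit", {
  set.seed(14)
  n <- 30
  e <- rnorm(n); m <- rnorm(n)
  y <- 1 + 0.5 * m - 0.3 * e + rnorm(n, 0.2)
  y_na <- y; y_na[c(3, 17)] <- NA
  f <- fit_univariate(y_na, e, m)
  keep <- -c(3, 17)
  o <- oracle_ols(y[keep], cbind(1, m[keep], e[keep]))
  expect_equal(f$n_used, n - 2L)
  expect_equal(c(f$alpha, f$beta, f$gamma), o$coef, tolerance = 1e-10)
})

test_that("fit_all_pairs equals per-pair fits, in both code paths", {
  coh <- toy_cohort(n_samples = 25, n_proteins = 2, n_mirnas = 3,
                    support = random_support(2, 3, 1, seed = 3),
                    noise_sd = 0.3, seed = 15)
  lg <- cohort_logs(coh)
  tab <- fit_all_pairs(lg$protein, lg$mrna, lg$mirna, coh$gene_map)
  expect_s3_class(tab, "univariate_table")
  expect_equal(nrow(tab), 6L)
  for (r in seq_len(nrow(tab))) {
    eid <- coh$gene_map$mrna[match(tab$protein[r], coh$gene_map$protein)]
    f <- fit_univariate(lg$protein[tab$protein[r], ], lg$mrna[eid, ],
                        lg$mirna[tab$mirna[r], ])
    expect_equal(tab$beta[r], f$beta, tolerance = 1e-9)
    expect_equal(tab$gamma[r], f$gamma, tolerance = 1e-9)
    expect_equal(tab$p_beta[r], f$p_beta, tolerance = 1e-9)
  }

  # NA in one miRNA row forces the slow path; results must agree with the
  # pairwise-deletion fit
  M2 <- unclass(lg$mirna); M2[1, 4] <- NA
  tab2 <- fit_all_pairs(lg$protein, lg$mrna,
                        expression_matrix(exp(M2), "miRNA") |> log_transform(),
                        coh$gene_map)
  f_na <- fit_univariate(lg$protein[1, ], lg$mrna[1, ], M2[1, ])
  r1 <- tab2[tab2$protein == "prot_001" & tab2$mirna == "mir_0001", ]
  expect_equal(r1$beta, f_na$beta, tolerance = 1e-9)
  expect_equal(r1$n_used, 24L)
})

test_that("fit_all_pairs is invariant to sample order and validates inputs", {
  coh <- toy_cohort(n_samples = 20, n_proteins = 2, n_mirnas = 4,
                    noise_sd = 0.2, seed = 16)
  lg <- cohort_logs(coh)
  tab <- fit_all_pairs(lg$protein, lg$mrna, lg$mirna, coh$gene_map)
  perm <- sample(ncol(lg$protein))
  tab_p <- fit_all_pairs(lg$protein[, perm], lg$mrna[, perm],
                         lg$mirna[, perm], coh$gene_map)
  expect_equal(tab$beta, tab_p$beta, tolerance = 1e-12)
  expect_equal(tab$p_beta, tab_p$p_beta, tolerance = 1e-12)

  bad_map <- data.frame(protein = "prot_001", mrna = "gene_001")
  expect_error(fit_all_pairs(lg$protein, lg$mrna, lg$mirna, bad_map),
               "without a mapped mRNA")
  m2 <- lg$mirna; colnames(m2) <- paste0("x", colnames(m2))
  expect_error(fit_all_pairs(lg$protein, lg$mrna, m2, coh$gene_map),
               "shared sample")
})

test_that("the conservative FDR estimator does its arithmetic", {
  p <- c(runif(10, 0, 0.05), runif(90, 0.2, 1))
  p[1:10] <- seq(0.001, 0.05, length.out = 10)
  r <- estimate_fdr(p, 0.05)
  expect_equal(r$N, 100L)
  expect_equal(r$S, 10L)
  expect_equal(r$fdr_hat, 100 * 0.05 / 10)

  expect_equal(estimate_fdr(rep(1, 20), 0.5)$fdr_hat, Inf)
  expect_error(estimate_fdr(numeric(0), 0.1), "no p-values")
  expect_error(estimate_fdr(c(0.5, 1.2), 0.1), "\\[0, 1\\]")
})

test_that("threshold search maximizes calls subject to the FDR bound", {
  p <- c(rep(1e-4, 50), rep(0.9, 50))
  r <- choose_threshold(p, 0.01)
  expect_equal(r$p_star, 1e-4)
  expect_equal(r$S, 50L)
  expect_equal(r$fdr_hat, 100 * 1e-4 / 50)

  # equivalence with the exhaustive-scan oracle on random instances
  set.seed(17)
  for (i in 1:25) {
    pv <- c(stats::rbeta(sample(20:200, 1), 0.3, 4),
            runif(sample(10:100, 1)))
    target <- sample(c(0.01, 0.05, 0.2), 1)
    got <- choose_threshold(pv, target)
    want <- oracle_choose_threshold(pv, target)
    expect_equal(got$S, want$S)
    expect_equal(got$p_star, want$p_star)
    expect_equal(got$fdr_hat, want$fdr_hat, tolerance = 1e-12)
  }
})

test_that("calls never shrink when the FDR bound is relaxed", {
  set.seed(18)
  pv <- c(rbeta(300, 0.2, 5), runif(700))
  S_prev <- -1L
  for (target in c(0.001, 0.01, 0.05, 0.1, 0.3)) {
    S <- choose_threshold(pv, target)$S
    expect_gte(S, S_prev)
    S_prev <- S
  }
})

test_that("call_significant recovers a strong planted signal", {
  sup <- random_support(4, 20, 5, betas = c(-1, 1), seed = 19)
  coh <- toy_cohort(n_samples = 283, n_proteins = 4, n_mirnas = 20,
                    support = sup, noise_sd = 0.1, seed = 20)
  lg <- cohort_logs(coh)
  tab <- fit_all_pairs(lg$protein, lg$mrna, lg$mirna, coh$gene_map)
  assoc <- call_significant(tab, 0.01)
  truth_sign <- sign(coh$truth$beta)
  called_sign <- assoc$sign
  # every true effect called with the right sign
  nz <- truth_sign != 0
  expect_true(all(called_sign[nz] == truth_sign[nz]))

  empty <- call_significant(tab, 0)
  expect_equal(sum(empty$significant), 0L)
  expect_true(all(empty$sign == 0))
})
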