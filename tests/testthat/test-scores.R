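mk_fit <- function(pid, betas, alpha = 0, gamma = 0) {
  structure(list(protein_id = pid, alpha_hat = alpha, gamma_hat = gamma,
                 beta_hats = betas, lambda = 0.1, cv_folds = 10L,
                 cv_seed = 1L, allowed_set = names(betas),
                 lambda_rule = "min"),
            class = "multivariate_fit")
}

mk_fits <- function(...) {
  fits <- list(...)
  structure(setNames(fits, vapply(fits, `[[`, "", "protein_id")),
            class = "multivariate_fits")
}

test_that("patient scores are the coefficient-weighted miRNA sums", {
  logM <- matrix(rnorm(3 * 5), 3, 5,
                 dimnames = list(c("m1", "m2", "m3"), paste0("s", 1:5)))
  fits <- mk_fits(mk_fit("p1", c(m1 = 1)),
                  mk_fit("p2", c(m1 = 1, m2 = -1)),
                  mk_fit("p3", setNames(numeric(0), character(0))))
  sc <- compute_scores(fits, logM)
  expect_equal(unname(sc["p1", ]), unname(logM["m1", ]))
  expect_equal(unname(sc["p2", ]), unname(logM["m1", ] - logM["m2", ]))
  expect_equal(unname(sc["p3", ]), rep(0, 5))   # empty support: zero row

  # double-loop oracle on a random instance
  set.seed(70)
  logM2 <- matrix(rnorm(6 * 9), 6, 9,
                  dimnames = list(paste0("m", 1:6), paste0("s", 1:9)))
  betas <- list(c(m2 = 0.5, m5 = -2), c(m1 = 1.5), c(m3 = 0.3, m6 = 1))
  fits2 <- do.call(mk_fits, lapply(seq_along(betas), function(i) {
    mk_fit(paste0("p", i), betas[[i]])
  }))
  sc2 <- compute_scores(fits2, logM2)
  for (i in seq_along(betas)) for (p in 1:9) {
    want <- 0
    for (m in names(betas[[i]])) want <- want + betas[[i]][[m]] * logM2[m, p]
    expect_equal(sc2[i, p], want, tolerance = 1e-12)
  }

  expect_error(compute_scores(mk_fits(mk_fit("p1", c(zz = 1))), logM),
               "missing from logM")
})

test_that("scores are linear in the coefficients", {
  set.seed(71)
  logM <- matrix(rnorm(4 * 7), 4, 7,
                 dimnames = list(paste0("m", 1:4), paste0("s", 1:7)))
  b1 <- c(m1 = 0.5, m3 = -1)
  b2 <- c(m1 = 0.2, m4 = 2)
  bsum <- c(m1 = 0.7, m3 = -1, m4 = 2)
  s1 <- compute_scores(mk_fits(mk_fit("p", b1)), logM)
  s2 <- compute_scores(mk_fits(mk_fit("p", b2)), logM)
  ssum <- compute_scores(mk_fits(mk_fit("p", bsum)), logM)
  expect_equal(unclass(ssum), unclass(s1) + unclass(s2), tolerance = 1e-10)
})

test_that("patients with orthogonal score profiles split cleanly", {
  prof1 <- c(5, 0, 0); prof2 <- c(0, 5, 0)
  scores <- cbind(s1 = prof1, s2 = prof1 + 0.01, s3 = prof2,
                  s4 = prof2 - 0.01)
  rownames(scores) <- paste0("p", 1:3)
  cl <- cluster_patients(scores, k = 2)
  expect_equal(cl$labels[["s1"]], cl$labels[["s2"]])
  expect_equal(cl$labels[["s3"]], cl$labels[["s4"]])
  expect_false(cl$labels[["s1"]] == cl$labels[["s3"]])
  expect_error(cluster_patients(scores[, 1, drop = FALSE]), ">= 2 patients")
})

test_that("subtype structure in the generator shows up in patient clusters", {
  aris <- vapply(1:5, function(rep) {
    sup <- random_support(6, 20, 3, betas = c(-1, 1), seed = rep)
    coh <- toy_cohort(n_samples = 80, n_proteins = 6, n_mirnas = 20,
                      support = sup, noise_sd = 0.2, n_subtypes = 2,
                      subtype_shift = c(0, 1.5), seed = 100 + rep)
    lg <- cohort_logs(coh)
    tab <- fit_all_pairs(lg$protein, lg$mrna, lg$mirna, coh$gene_map)
    fits <- fit_all_multivariate(lg$protein, lg$mrna, lg$mirna,
                                 coh$gene_map, tab, cv_seed = rep)
    sc <- compute_scores(fits, lg$mirna)
    cl <- cluster_patients(sc, k = 2)
    adjusted_rand(cl$labels[colnames(sc)], coh$truth$subtype)
  }, numeric(1))
  expect_gte(mean(aris), 0.8)
})

test_that("cluster-clinical association testing behaves at the extremes", {
  # perfect alignment
  lab <- rep(1:2, each = 20)
  clin <- rep(c("pos", "neg"), each = 20)
  r <- cluster_vs_clinical(lab, clin)
  expect_lt(r$p_value, 0.001)

  # exact independence
  r2 <- cluster_vs_clinical(rep(1:2, each = 20),
                            rep(c("a", "b"), times = 20))
  expect_equal(r2$p_value, 1, tolerance = 1e-12)

  expect_error(cluster_vs_clinical(rep(1, 10), rep("a", 10)),
               ">= 2 categories")
})

test_that("null clinical labels give approximately uniform p-values", {
  set.seed(72)
  ps <- replicate(200, {
    cluster_vs_clinical(sample(1:2, 200, replace = TRUE),
                        sample(c("a", "b"), 200, replace = TRUE))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("self-prediction on noise-free data is exact", {
  coh <- toy_cohort(n_samples = 100, n_proteins = 1, n_mirnas = 6,
                    support = list(c("2" = -1, "5" = 0.8)), gamma = 1.2,
                    alpha = 0.4, noise_sd = 0, seed = 73)
  lg <- cohort_logs(coh)
  fit <- fit_multivariate(lg$protein[1, ], lg$mrna[1, ], t(lg$mirna),
                          lambda = 0)
  pr <- predict_protein(fit, lg$mrna[1, ], unclass(lg$mirna),
                        lg$protein[1, ])
  expect_equal(pr$predicted, lg$protein[1, ], tolerance = 1e-8)
  expect_equal(pr$result$r, 1, tolerance = 1e-10)
})

test_that("prediction drops missing miRNAs and reports the accounting", {
  coh <- toy_cohort(n_samples = 50, n_proteins = 1, n_mirnas = 4,
                    support = list(c("1" = 1, "3" = -1)), noise_sd = 0.1,
                    seed = 74)
  lg <- cohort_logs(coh)
  fit <- mk_fit("prot_001", c(mir_0001 = 1, mir_0003 = -1), gamma = 1)
  logM_partial <- unclass(lg$mirna)[c("mir_0001", "mir_0002"), ]
  pr <- predict_protein(fit, lg$mrna[1, ], logM_partial, lg$protein[1, ])
  expect_equal(pr$result$n_mirnas_used, 1L)
  expect_equal(pr$result$n_mirnas_missing, 1L)
  expect_equal(pr$predicted,
               1 * lg$mrna[1, ] + 1 * logM_partial["mir_0001", ],
               tolerance = 1e-12)

  # empty support and gamma = 1: prediction is logE up to the intercept
  fit0 <- mk_fit("prot_001", setNames(numeric(0), character(0)), gamma = 1)
  pr0 <- predict_protein(fit0, lg$mrna[1, ], logM_partial, lg$protein[1, ])
  expect_equal(pr0$result$r,
               unname(cor(lg$mrna[1, ], lg$protein[1, ])),
               tolerance = 1e-10)
})

test_that("cross-cohort prediction improves as generative noise shrinks", {
  sup <- random_support(5, 15, 3, betas = c(-1, 1), seed = 75)
  med_r <- vapply(c(0.5, 0.25, 0.1), function(nsd) {
    cfgA <- simulation_config(120, 5, 15, support = sup, noise_sd = nsd,
                              seed = 76)
    cfgB <- simulation_config(120, 5, 15, support = sup, noise_sd = nsd,
                              seed = 77)
    A <- simulate_cohort(cfgA); B <- simulate_cohort(cfgB)
    la <- cohort_logs(A); lb <- cohort_logs(B)
    tab <- fit_all_pairs(la$protein, la$mrna, la$mirna, A$gene_map)
    fits <- fit_all_multivariate(la$protein, la$mrna, la$mirna,
                                 A$gene_map, tab, cv_seed = 1)
    res <- predict_cohort(fits, lb$mrna, lb$mirna, lb$protein, B$gene_map)
    median(res$r)
  }, numeric(1))
  expect_true(all(diff(med_r) > 0))
})

test_that("screen z-scoring standardizes each protein across the screen", {
  set.seed(78)
  raw <- matrix(rnorm(50 * 3, mean = 5, sd = 2), 50, 3,
                dimnames = list(paste0("m", 1:50), paste0("p", 1:3)))
  z <- screen_zscore(raw)
  expect_equal(unname(colMeans(z$z)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(z$z, 2, sd)), rep(1, 3), tolerance = 1e-12)

  # a value at the screen mean maps to 0; mean + 2 SD maps to 2
  mu <- mean(raw[, 1]); s <- sd(raw[, 1])
  raw2 <- raw; raw2[1, 1] <- mu
  expect_lt(abs(screen_zscore(raw2)$z[1, 1]), 0.05)

  bad <- raw; bad[, 2] <- 3
  expect_error(screen_zscore(bad), "zero screen standard deviation")
})

test_that("screen consistency demands significance, magnitude and sign", {
  beta <- matrix(c(0.5, 0.5, 0.5, -0.5), 1, 4,
                 dimnames = list("p1", paste0("m", 1:4)))
  sig <- matrix(c(TRUE, TRUE, TRUE, FALSE), 1, 4)
  assoc <- association_matrix(beta, sig)
  zmat <- matrix(c(2.5, -2.5, 1.5, 2.5), 4, 1,
                 dimnames = list(paste0("m", 1:4), "p1"))
  z <- structure(list(z = zmat, threshold = 1.96),
                 class = "screen_zscores")
  out <- screen_consistency(assoc, z)
  val <- setNames(out$validated, out$mirna)
  expect_true(val[["m1"]])     # positive beta, z = +2.5
  expect_false(val[["m2"]])    # inconsistent sign
  expect_false(val[["m3"]])    # |z| below threshold
  expect_false("m4" %in% out$mirna)   # not significant: not considered
})
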