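# Independent brute-force oracles used across the suite. These deliberately
# take the slow, obvious route so they cannot share a bug with the package's
# optimized paths.

# OLS via the normal equations: coef = (X'X)^{-1} X'y, with two-sided t-test
# p-values computed from first principles.
oracle_ols <- function(y, X) {
  xtx_inv <- solve(t(X) %*% X)
  coef <- as.numeric(xtx_inv %*% t(X) %*% y)
  res <- y - as.numeric(X %*% coef)
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- unname(sqrt(sigma2 * diag(xtx_inv)))
  p <- unname(2 * stats::pt(-abs(coef / se), df))
  list(coef = unname(coef), se = se, p = p)
}

# Exhaustive scan over observed p-values for the FDR threshold search.
oracle_choose_threshold <- function(p, target) {
  N <- length(p)
  best <- list(S = 0L, p_star = 0, fdr_hat = 0)
  for (cand in sort(unique(p))) {
    S <- sum(p <= cand)
    fdr <- N * cand / S
    if (fdr <= target && S > best$S) {
      best <- list(S = S, p_star = cand, fdr_hat = fdr)
    }
  }
  best
}

# Naive O(n^3) complete-linkage agglomeration; returns the cophenetic
# distance matrix (height at which each pair first shares a cluster), which
# fully characterizes the merge tree.
oracle_complete_linkage_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1L]) best <- c(h, i, j)
      }
    }
    i <- best[2L]; j <- best[3L]
    coph[clusters[[i]], clusters[[j]]] <- best[1L]
    coph[clusters[[j]], clusters[[i]]] <- best[1L]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  coph
}

# Adjusted Rand index between two partitions.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / choose2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Fraction of pairs on which two partitions agree about co-membership.
pair_agreement <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, `==`)[upper.tri(diag(n))]
  same_b <- outer(b, b, `==`)[upper.tri(diag(n))]
  mean(same_a == same_b)
}
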