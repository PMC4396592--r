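# Univariate association screen.
#
# For protein i and miRNA k the model on the log scale is
#     log P_i = alpha + beta log M_k + gamma log E_i + eps,
# fitted by ordinary least squares for every (protein, miRNA) pair; the mRNA
# term absorbs the in-cis effect so that beta measures the miRNA association
# net of transcript abundance. Significance over the pooled screen is called
# with the conservative estimator FDR = N * P_star / S (expected false
# positives under a global null over observed positives).

check_log_scale <- function(x, name) {
  if (!is.numeric(x)) stop(sprintf("`%s` must be numeric", name), call. = FALSE)
  invisible(x)
}

#' Fit the power-law model for one protein/miRNA pair
#'
#' Ordinary least squares of `logP` on an intercept, `logM` and `logE`,
#' with two-sided t-test p-values (df = n - 3) for the miRNA exponent `beta`
#' and the mRNA exponent `gamma`. Samples with a missing value in any of the
#' three vectors are excluded pairwise. A collinear design or fewer than 4
#' usable samples yields a fit flagged `degenerate` with p-values 1, so a
#' genome-scale sweep never aborts on one bad pair.
#'
#' @param logP,logE,logM Equal-length numeric vectors on the log scale
#'   (protein, in-cis mRNA, miRNA).
#' @param protein_id,mirna_id Optional identifiers carried into the result.
#' @return One-row data frame with columns `protein`, `mirna`, `alpha`,
#'   `beta`, `gamma`, `p_beta`, `p_gamma`, `n_used`, `degenerate`.
#' @export
fit_univariate <- function(logP, logE, logM,
                           protein_id = NA_character_,
                           mirna_id = NA_character_) {
  check_log_scale(logP, "logP"); check_log_scale(logE, "logE")
  check_log_scale(logM, "logM")
  if (length(logP) != length(logE) || length(logP) != length(logM)) {
    stop("logP, logE and logM must have equal length", call. = FALSE)
  }
  ok <- stats::complete.cases(logP, logE, logM)
  y <- logP[ok]; e <- logE[ok]; m <- logM[ok]
  n <- length(y)
  degen_row <- function() {
    data.frame(protein = protein_id, mirna = mirna_id,
               alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
               p_beta = 1, p_gamma = 1, n_used = n, degenerate = TRUE,
               stringsAsFactors = FALSE)
  }
  if (n < 4L) {
    warning(sprintf("pair (%s, %s): only %d usable samples (need >= 4); %s",
                    protein_id, mirna_id, n, "fit skipped"), call. = FALSE)
    return(degen_row())
  }
  X <- cbind(`(Intercept)` = 1, logM = m, logE = e)
  qx <- qr(X)
  if (qx$rank < 3L) return(degen_row())
  coef <- qr.coef(qx, y)
  res <- y - X %*% coef
  rss <- sum(res^2)
  df <- n - 3L
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(pmax(sigma2 * diag(xtx_inv), 0))
  pval <- function(est, s) {
    if (s == 0) return(if (abs(est) > 0) 0 else 1)
    2 * stats::pt(-abs(est / s), df)
  }
  data.frame(protein = protein_id, mirna = mirna_id,
             alpha = coef[1L], beta = coef[2L], gamma = coef[3L],
             p_beta = pval(coef[2L], se[2L]),
             p_gamma = pval(coef[3L], se[3L]),
             n_used = n, degenerate = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit the univariate model for every protein x miRNA pair
#'
#' Runs [fit_univariate()] over the full grid. When the inputs are free of
#' missing values, a vectorized centered-sums path solves all pairs for one
#' protein at once; it is algebraically identical to the per-pair QR fit.
#' Matrices must already be log-transformed (see [log_transform()]) and are
#' aligned on their shared sample IDs.
#'
#' @param protein,mrna,mirna Log-scale [expression_matrix()] objects
#'   (features x samples).
#' @param gene_map Data frame with columns `protein` and `mrna` pairing each
#'   protein to its in-cis transcript.
#' @return A data frame of class `univariate_table` with one row per
#'   (protein, miRNA) pair, protein-major order; attributes `n_proteins`,
#'   `n_mirnas`.
#' @export
fit_all_pairs <- function(protein, mrna, mirna, gene_map) {
  stopifnot(is.matrix(protein), is.matrix(mrna), is.matrix(mirna))
  if (!all(c("protein", "mrna") %in% names(gene_map))) {
    stop("`gene_map` needs columns `protein` and `mrna`", call. = FALSE)
  }
  missing_map <- setdiff(rownames(protein), gene_map$protein)
  if (length(missing_map)) {
    stop("protein(s) without a mapped mRNA: ",
         paste(utils::head(missing_map, 5L), collapse = ", "), call. = FALSE)
  }
  missing_mrna <- setdiff(gene_map$mrna[match(rownames(protein),
                                              gene_map$protein)],
                          rownames(mrna))
  if (length(missing_mrna)) {
    stop("mapped mRNA(s) absent from the mRNA matrix: ",
         paste(utils::head(missing_mrna, 5L), collapse = ", "), call. = FALSE)
  }
  samples <- Reduce(intersect, list(colnames(protein), colnames(mrna),
                                    colnames(mirna)))
  if (length(samples) == 0L) stop("no shared sample IDs", call. = FALSE)
  P <- protein[, samples, drop = FALSE]
  E <- mrna[, samples, drop = FALSE]
  M <- mirna[, samples, drop = FALSE]
  prot_ids <- rownames(P)
  mir_ids <- rownames(M)
  nm <- length(mir_ids)
  mir_has_na <- apply(M, 1L, anyNA)

  per_protein <- function(i) {
    pid <- prot_ids[i]
    eid <- gene_map$mrna[match(pid, gene_map$protein)]
    y_full <- P[i, ]; e_full <- E[eid, ]
    ok <- !(is.na(y_full) | is.na(e_full))
    fast_idx <- which(!mir_has_na)
    slow_idx <- which(mir_has_na)
    out <- vector("list", 2L)
    if (length(fast_idx)) {
      y <- y_full[ok]; e <- e_full[ok]
      L <- M[fast_idx, ok, drop = FALSE]
      n <- length(y)
      if (n < 4L) {
        out[[1L]] <- do.call(rbind, lapply(fast_idx, function(j) {
          fit_univariate(y_full, e_full, M[j, ], pid, mir_ids[j])
        }))
      } else {
        ybar <- mean(y); ebar <- mean(e)
        yc <- y - ybar; ec <- e - ebar
        mbar <- rowMeans(L)
        Lc <- L - mbar
        Smm <- rowSums(Lc^2)
        Sme <- as.vector(Lc %*% ec)
        Smy <- as.vector(Lc %*% yc)
        See <- sum(ec^2)
        Sey <- sum(ec * yc)
        Syy <- sum(yc^2)
        det <- Smm * See - Sme^2
        # relative rank check: collinearity or constant predictors
        degen <- !is.finite(det) | det <= 1e-12 * pmax(Smm * See, 1e-300)
        beta <- (Smy * See - Sey * Sme) / det
        gam <- (Sey * Smm - Smy * Sme) / det
        alpha <- ybar - beta * mbar - gam * ebar
        rss <- pmax(Syy - beta * Smy - gam * Sey, 0)
        df <- n - 3L
        sigma2 <- rss / df
        se_b <- sqrt(pmax(sigma2 * See / det, 0))
        se_g <- sqrt(pmax(sigma2 * Smm / det, 0))
        p_b <- ifelse(se_b > 0, 2 * stats::pt(-abs(beta / se_b), df),
                      ifelse(abs(beta) > 0, 0, 1))
        p_g <- ifelse(se_g > 0, 2 * stats::pt(-abs(gam / se_g), df),
                      ifelse(abs(gam) > 0, 0, 1))
        beta[degen] <- NA_real_; gam[degen] <- NA_real_
        alpha[degen] <- NA_real_
        p_b[degen] <- 1; p_g[degen] <- 1
        out[[1L]] <- data.frame(
          protein = pid, mirna = mir_ids[fast_idx],
          alpha = alpha, beta = beta, gamma = gam,
          p_beta = p_b, p_gamma = p_g, n_used = n, degenerate = degen,
          stringsAsFactors = FALSE)
      }
    }
    if (length(slow_idx)) {
      out[[2L]] <- do.call(rbind, lapply(slow_idx, function(j) {
        fit_univariate(y_full, e_full, M[j, ], pid, mir_ids[j])
      }))
    }
    res <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
    res[match(mir_ids, res$mirna), , drop = FALSE]
  }

  tab <- do.call(rbind, lapply(seq_along(prot_ids), per_protein))
  rownames(tab) <- NULL
  n_degen <- sum(tab$degenerate)
  if (n_degen > 0L) {
    message(sprintf("%d of %d fits degenerate (p-values set to 1)",
                    n_degen, nrow(tab)))
  }
  structure(tab, n_proteins = length(prot_ids), n_mirnas = nm,
            class = c("univariate_table", "data.frame"))
}

#' Conservative FDR estimate at a fixed p-value threshold
#'
#' Assuming independent tests and a global null, the expected number of false
#' positives at threshold `p_star` is `N * p_star`; dividing by the observed
#' number of calls `S` gives the most conservative FDR estimate
#' `N * p_star / S`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param p_star Threshold.
#' @return A list of class `fdr_result`: `N`, `p_star`, `S`, `fdr_hat`
#'   (`Inf` when `S == 0`).
#' @export
estimate_fdr <- function(p_values, p_star) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0L) stop("no p-values supplied", call. = FALSE)
  if (any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  assert_scalar_number(p_star, "p_star", lower = 0, upper = 1)
  N <- length(p_values)
  S <- sum(p_values <= p_star)
  structure(list(N = N, p_star = p_star, S = S,
                 fdr_hat = if (S > 0) N * p_star / S else Inf),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("FDR: N = %d, P* = %g, S = %d, FDR-hat = %g\n",
              x$N, x$p_star, x$S, x$fdr_hat))
  invisible(x)
}

#' Choose the p-value threshold holding the estimated FDR below a bound
#'
#' Scans the observed p-values as candidate thresholds (any threshold between
#' consecutive order statistics induces the same call set, so observed values
#' are canonical) and returns the feasible threshold maximizing the number of
#' calls `S` subject to `N * p_star / S <= target_fdr`. If no threshold
#' qualifies, the result has `S = 0`, `p_star = 0` and `fdr_hat = 0`.
#'
#' @param p_values Numeric vector of p-values.
#' @param target_fdr Upper bound on the estimated FDR, in `(0, 1)`.
#' @return An `fdr_result` with an extra `target_fdr` field.
#' @export
choose_threshold <- function(p_values, target_fdr = 0.01) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0L) stop("no p-values supplied", call. = FALSE)
  assert_scalar_number(target_fdr, "target_fdr", lower = 0, upper = 1,
                       strict_lower = TRUE)
  N <- length(p_values)
  ps <- sort(unique(p_values))
  S_at <- findInterval(ps, sort(p_values))   # calls at each candidate
  fdr_at <- N * ps / S_at
  feas <- which(fdr_at <= target_fdr)
  if (length(feas) == 0L) {
    res <- list(N = N, p_star = 0, S = 0L, fdr_hat = 0)
  } else {
    best <- feas[which.max(S_at[feas])]
    res <- list(N = N, p_star = ps[best], S = S_at[best],
                fdr_hat = fdr_at[best])
  }
  res$target_fdr <- target_fdr
  structure(res, class = "fdr_result")
}

#' Association matrix: the proteins x miRNAs coefficient table B
#'
#' @param beta Numeric proteins x miRNAs matrix of miRNA exponents (dimnames
#'   required).
#' @param significant Logical mask of the same shape; `NA` beta cells cannot
#'   be significant.
#' @param fdr Optional `fdr_result` documenting how the mask was derived.
#' @return A list of class `association_matrix` with `beta`, `significant`
#'   and `sign` (-1/0/+1, nonzero exactly on the significant cells).
#' @export
association_matrix <- function(beta, significant, fdr = NULL) {
  stopifnot(is.matrix(beta),
            identical(dim(beta), dim(significant)))
  significant <- significant & !is.na(beta)
  sgn <- matrix(0L, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  sgn[significant] <- sign(beta[significant])
  structure(list(beta = beta, significant = significant, sign = sgn,
                 fdr = fdr), class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf(
    "<association_matrix: %d proteins x %d miRNAs, %d significant (%d neg / %d pos)>\n",
    nrow(x$beta), ncol(x$beta), sum(x$significant),
    sum(x$sign < 0), sum(x$sign > 0)))
  invisible(x)
}

#' Call significant miRNA-protein associations at a target FDR
#'
#' Pools the miRNA p-values of the whole screen, picks the threshold with
#' [choose_threshold()] and assembles the [association_matrix()].
#'
#' @param table A `univariate_table` from [fit_all_pairs()].
#' @param target_fdr FDR bound (default 0.01); `0` yields an empty mask.
#' @return An [association_matrix()].
#' @export
call_significant <- function(table, target_fdr = 0.01) {
  stopifnot(inherits(table, "univariate_table"))
  prot_ids <- unique(table$protein)
  mir_ids <- unique(table$mirna)
  beta <- matrix(NA_real_, length(prot_ids), length(mir_ids),
                 dimnames = list(prot_ids, mir_ids))
  beta[cbind(match(table$protein, prot_ids),
             match(table$mirna, mir_ids))] <- table$beta
  if (target_fdr <= 0) {
    sig <- matrix(FALSE, nrow(beta), ncol(beta), dimnames = dimnames(beta))
    return(association_matrix(beta, sig,
                              structure(list(N = nrow(table), p_star = 0,
                                             S = 0L, fdr_hat = 0,
                                             target_fdr = 0),
                                        class = "fdr_result")))
  }
  fdr <- choose_threshold(table$p_beta, target_fdr)
  sig <- matrix(FALSE, nrow(beta), ncol(beta), dimnames = dimnames(beta))
  called <- table$p_beta <= fdr$p_star & fdr$S > 0
  sig[cbind(match(table$protein, prot_ids),
            match(table$mirna, mir_ids))] <- called
  association_matrix(beta, sig, fdr)
}
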