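# Prescreen-constrained multivariate model.
#
# Per protein, all miRNAs enter one model on the log scale,
#     log P = alpha + sum_j beta_j log M_j + gamma log E + eps,
# with a mild restriction: miRNAs nominally nonsignificant in the univariate
# screen (p > alpha_level, default 0.01, uncorrected) are constrained to
# beta_j = 0. The remaining coefficients are estimated by the Lasso with the
# penalty chosen by k-fold cross-validation; the intercept and the in-cis
# mRNA coefficient gamma are unpenalized by default, because the mRNA term is
# an adjustment, not a selectable predictor. Nonzero Lasso coefficients are
# the screen's "significant effects".

#' miRNAs allowed into the multivariate model for one protein
#'
#' @param table A `univariate_table` from [fit_all_pairs()].
#' @param protein_id Protein identifier present in the table.
#' @param alpha_level Nominal univariate significance cutoff (default 0.01,
#'   no multiplicity correction).
#' @return Character vector of miRNA IDs with `p_beta <= alpha_level`.
#' @export
prescreen <- function(table, protein_id, alpha_level = 0.01) {
  stopifnot(inherits(table, "univariate_table"))
  assert_scalar_number(alpha_level, "alpha_level", lower = 0, upper = 1)
  rows <- table[table$protein == protein_id, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("unknown protein: ", protein_id, call. = FALSE)
  }
  rows$mirna[!is.na(rows$p_beta) & rows$p_beta <= alpha_level]
}

#' Lasso fit of the multivariate model for one protein
#'
#' L1-penalized least squares of `logP` on `logE` plus the allowed miRNAs.
#' The penalty `lambda` is chosen by `cv_folds`-fold cross-validation with a
#' fold assignment derived deterministically from `cv_seed` (lambda at
#' minimum mean CV error by default; `lambda_rule = "1se"` for the one-SE
#' convention). Predictors are standardized internally by the solver and
#' coefficients back-transformed. An empty allowed set degrades to ordinary
#' least squares of `logP` on `logE` alone.
#'
#' @param logP,logE Equal-length numeric vectors on the log scale.
#' @param logM_allowed Samples x allowed-miRNA numeric matrix (0 columns for
#'   an empty allowed set); column names are the miRNA IDs.
#' @param cv_folds Number of CV folds (>= 2, default 10).
#' @param cv_seed Integer seed controlling the fold assignment.
#' @param lambda Optional fixed penalty, bypassing cross-validation (used by
#'   the limit checks; `0` reproduces the unpenalized fit).
#' @param penalize_gamma Penalize the mRNA coefficient like the miRNAs
#'   (default `FALSE`).
#' @param lambda_rule `"min"` (default) or `"1se"`.
#' @param protein_id Optional identifier carried into the result.
#' @return A list of class `multivariate_fit`: `protein_id`, `alpha_hat`,
#'   `gamma_hat`, `beta_hats` (named vector of nonzero miRNA coefficients),
#'   `lambda`, `cv_folds`, `cv_seed`, `allowed_set`, `lambda_rule`.
#' @export
fit_multivariate <- function(logP, logE, logM_allowed,
                             cv_folds = 10L, cv_seed = 1L, lambda = NULL,
                             penalize_gamma = FALSE,
                             lambda_rule = c("min", "1se"),
                             protein_id = NA_character_) {
  lambda_rule <- match.arg(lambda_rule)
  if (is.null(dim(logM_allowed))) {
    logM_allowed <- matrix(logM_allowed, nrow = length(logP))
  }
  n <- length(logP)
  stopifnot(length(logE) == n, nrow(logM_allowed) == n)
  if (is.null(lambda)) {
    if (cv_folds < 2L) stop("cv_folds must be >= 2", call. = FALSE)
    if (n <= cv_folds) stop("need more samples than CV folds", call. = FALSE)
  }
  m <- ncol(logM_allowed)
  allowed <- colnames(logM_allowed) %||% character(0)

  result <- function(alpha_hat, gamma_hat, beta_hats, lam) {
    structure(list(protein_id = protein_id, alpha_hat = alpha_hat,
                   gamma_hat = gamma_hat, beta_hats = beta_hats,
                   lambda = lam, cv_folds = cv_folds, cv_seed = cv_seed,
                   allowed_set = allowed, lambda_rule = lambda_rule),
              class = "multivariate_fit")
  }

  if (m == 0L) {
    fit <- stats::lm.fit(cbind(1, logE), logP)
    return(result(fit$coefficients[1L], fit$coefficients[2L],
                  stats::setNames(numeric(0), character(0)), NA_real_))
  }

  X <- cbind(logE, logM_allowed)
  colnames(X) <- c(".logE", allowed)
  pf <- c(if (penalize_gamma) 1 else 0, rep(1, m))

  if (!is.null(lambda)) {
    assert_scalar_number(lambda, "lambda", lower = 0)
    # glmnet wants a decreasing path; anchor it at the requested value
    sx <- scale(X)
    lmax <- max(abs(crossprod(sx[, pf > 0, drop = FALSE],
                              logP - mean(logP)))) / n
    lmax <- max(lmax * 1.1, lambda * 2, 1e-3)
    path <- exp(seq(log(lmax), log(max(lambda, lmax * 1e-6)), length.out = 80))
    path <- sort(unique(c(path, lambda)), decreasing = TRUE)
    fit <- glmnet::glmnet(X, logP, family = "gaussian", alpha = 1,
                          penalty.factor = pf, lambda = path,
                          standardize = TRUE, thresh = 1e-12,
                          maxit = 1e5)
    co <- as.matrix(stats::coef(fit, s = lambda, exact = TRUE, x = X,
                                y = logP, penalty.factor = pf,
                                thresh = 1e-12))[, 1L]
    lam <- lambda
  } else {
    foldid <- with_seed(cv_seed, sample(rep_len(seq_len(cv_folds), n)))
    cv <- glmnet::cv.glmnet(X, logP, family = "gaussian", alpha = 1,
                            penalty.factor = pf, foldid = foldid,
                            standardize = TRUE, thresh = 1e-7, maxit = 1e5)
    lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
    co <- as.matrix(stats::coef(cv, s = lam))[, 1L]
  }
  betas <- co[allowed]
  betas <- betas[betas != 0]
  result(co[["(Intercept)"]], co[[".logE"]],
         stats::setNames(as.numeric(betas), names(betas)), lam)
}

#' @export
print.multivariate_fit <- function(x, ...) {
  cat(sprintf(
    "<multivariate_fit %s: gamma = %.3f, %d/%d miRNAs selected, lambda = %s>\n",
    x$protein_id, x$gamma_hat, length(x$beta_hats), length(x$allowed_set),
    format(x$lambda, digits = 4)))
  invisible(x)
}

#' Fit the prescreened multivariate model for every protein
#'
#' Orchestrates [prescreen()] and [fit_multivariate()] over all proteins of a
#' cohort. Deterministic for a fixed `cv_seed`.
#'
#' @param protein,mrna,mirna Log-scale [expression_matrix()] objects with
#'   shared sample IDs.
#' @param gene_map Data frame pairing `protein` to `mrna` IDs.
#' @param table A `univariate_table` from [fit_all_pairs()] on the same data.
#' @param alpha_level Univariate prescreen cutoff (default 0.01).
#' @inheritParams fit_multivariate
#' @return A list of class `multivariate_fits`, one `multivariate_fit` per
#'   protein, named by protein ID.
#' @export
fit_all_multivariate <- function(protein, mrna, mirna, gene_map, table,
                                 alpha_level = 0.01, cv_folds = 10L,
                                 cv_seed = 1L, penalize_gamma = FALSE,
                                 lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  samples <- Reduce(intersect, list(colnames(protein), colnames(mrna),
                                    colnames(mirna)))
  if (length(samples) == 0L) stop("no shared sample IDs", call. = FALSE)
  P <- protein[, samples, drop = FALSE]
  E <- mrna[, samples, drop = FALSE]
  M <- mirna[, samples, drop = FALSE]
  fits <- lapply(rownames(P), function(pid) {
    eid <- gene_map$mrna[match(pid, gene_map$protein)]
    allowed <- prescreen(table, pid, alpha_level)
    fit_multivariate(P[pid, ], E[eid, ],
                     t(M[allowed, , drop = FALSE]),
                     cv_folds = cv_folds, cv_seed = cv_seed,
                     penalize_gamma = penalize_gamma,
                     lambda_rule = lambda_rule, protein_id = pid)
  })
  structure(stats::setNames(fits, rownames(P)), class = "multivariate_fits")
}

#' Nonzero multivariate coefficients as a long table
#'
#' @param fits A `multivariate_fits` collection.
#' @return Data frame with columns `protein`, `mirna`, `beta`.
#' @export
multivariate_coefs <- function(fits) {
  stopifnot(inherits(fits, "multivariate_fits"))
  rows <- lapply(fits, function(f) {
    if (length(f$beta_hats) == 0L) return(NULL)
    data.frame(protein = f$protein_id, mirna = names(f$beta_hats),
               beta = as.numeric(f$beta_hats), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) {
    out <- data.frame(protein = character(0), mirna = character(0),
                      beta = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
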