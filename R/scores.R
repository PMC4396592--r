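# Patient-specific miRNA-effect scores, clinical association, cross-cohort
# prediction and overexpression-screen consistency.
#
# The score of protein i in patient p summarizes the total modeled miRNA
# effect: score(i, p) = sum_j beta_ij * logM(j, p), using the multivariate
# coefficients and the log-standardized miRNA expression the coefficients
# were fitted on. Patients are clustered on these scores with Euclidean
# distance and complete linkage.

#' Patient-specific miRNA-effect scores
#'
#' @param fits A `multivariate_fits` collection (see
#'   [fit_all_multivariate()]).
#' @param logM Log-scale miRNA matrix (features x samples) on the same
#'   representation the coefficients were fitted on.
#' @return A proteins x samples numeric matrix of class `score_matrix`; a
#'   protein with no selected miRNA has an all-zero row.
#' @export
compute_scores <- function(fits, logM) {
  stopifnot(inherits(fits, "multivariate_fits"), is.matrix(logM))
  needed <- unique(unlist(lapply(fits, function(f) names(f$beta_hats))))
  absent <- setdiff(needed, rownames(logM))
  if (length(absent)) {
    stop("miRNA(s) missing from logM: ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  }
  scores <- matrix(0, length(fits), ncol(logM),
                   dimnames = list(names(fits), colnames(logM)))
  for (i in seq_along(fits)) {
    b <- fits[[i]]$beta_hats
    if (length(b) == 0L) next
    scores[i, ] <- as.numeric(b %*% logM[names(b), , drop = FALSE])
  }
  structure(scores, class = c("score_matrix", "matrix", "array"))
}

#' Cluster patients on their miRNA-effect scores
#'
#' Columns (patients) are clustered with Euclidean distance and complete
#' linkage; reuses the interactome tree machinery.
#'
#' @param scores A [compute_scores()] matrix.
#' @param k Optional cluster count; when given, flat labels are returned too.
#' @return A list with `tree` (hclust) and, if `k` is given, `labels`.
#' @export
cluster_patients <- function(scores, k = NULL) {
  stopifnot(is.matrix(scores))
  if (ncol(scores) < 2L) stop("need >= 2 patients", call. = FALSE)
  d <- stats::dist(t(scores), method = "euclidean")
  tree <- hierarchical_cluster(d, linkage = "complete")
  out <- list(tree = tree)
  if (!is.null(k)) out$labels <- extract_clusters(tree, k)
  out
}

#' Test association between cluster assignment and a clinical variable
#'
#' Chi-square test of independence on the contingency table; when any
#' expected cell count is below 5 and the table is small, Fisher's exact test
#' is used instead.
#'
#' @param labels Cluster labels (vector, aligned with `clinical`).
#' @param clinical Categorical clinical labels (e.g. HER2 or ER status).
#' @return A list with `table` (the contingency table), `p_value`, `method`.
#' @export
cluster_vs_clinical <- function(labels, clinical) {
  stopifnot(length(labels) == length(clinical))
  keep <- !is.na(labels) & !is.na(clinical)
  tab <- table(cluster = labels[keep], clinical = clinical[keep])
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("need >= 2 categories on both axes", call. = FALSE)
  }
  suppressWarnings(cs <- stats::chisq.test(tab, correct = FALSE))
  if (any(cs$expected < 5) && nrow(tab) <= 5L && ncol(tab) <= 5L) {
    p <- stats::fisher.test(tab, workspace = 2e6)$p.value
    method <- "fisher"
  } else {
    p <- cs$p.value
    method <- "chisq"
  }
  list(table = tab, p_value = p, method = method)
}

#' Predict protein expression in another cohort from fitted coefficients
#'
#' `prediction = alpha_hat + gamma_hat * logE_B + sum_j beta_j * logM_B(j)`,
#' with miRNAs absent from the target cohort dropped from the sum (and
#' counted). The prediction is compared with the observed log protein by
#' Pearson correlation with a two-sided t-approximation p-value.
#'
#' @param fit A `multivariate_fit` estimated on cohort A.
#' @param logE_B Numeric vector: the in-cis mRNA of the protein in cohort B,
#'   log scale, standardized with the same delta0 pipeline.
#' @param logM_B Log-scale miRNA matrix of cohort B (features x samples).
#' @param logP_B Optional observed log protein vector for validation.
#' @return A list with `predicted` (numeric vector) and, when `logP_B` is
#'   given, `result`: a one-row data frame `protein`, `r`, `p`, `n`,
#'   `n_mirnas_used`, `n_mirnas_missing`.
#' @export
predict_protein <- function(fit, logE_B, logM_B, logP_B = NULL) {
  stopifnot(inherits(fit, "multivariate_fit"), is.matrix(logM_B))
  b <- fit$beta_hats
  present <- intersect(names(b), rownames(logM_B))
  missing_n <- length(b) - length(present)
  if (length(present) == 0L && fit$gamma_hat == 0) {
    warning("degenerate prediction: no overlapping miRNAs and gamma = 0",
            call. = FALSE)
  }
  pred <- fit$alpha_hat + fit$gamma_hat * logE_B
  if (length(present)) {
    pred <- pred + as.numeric(b[present] %*%
                                logM_B[present, , drop = FALSE])
  }
  out <- list(predicted = pred)
  if (!is.null(logP_B)) {
    ok <- stats::complete.cases(pred, logP_B)
    n <- sum(ok)
    if (n < 3L) stop("need >= 3 samples to correlate", call. = FALSE)
    ct <- suppressWarnings(stats::cor.test(pred[ok], logP_B[ok]))
    out$result <- data.frame(
      protein = fit$protein_id, r = unname(ct$estimate), p = ct$p.value,
      n = n, n_mirnas_used = length(present), n_mirnas_missing = missing_n,
      stringsAsFactors = FALSE)
  }
  out
}

#' Cross-cohort prediction for a whole fit collection
#'
#' @param fits A `multivariate_fits` collection from cohort A.
#' @param mrna_B,mirna_B,protein_B Log-scale matrices of cohort B.
#' @param gene_map Protein-to-mRNA pairing valid in cohort B.
#' @return Data frame of per-protein prediction results (see
#'   [predict_protein()]).
#' @export
predict_cohort <- function(fits, mrna_B, mirna_B, protein_B, gene_map) {
  stopifnot(inherits(fits, "multivariate_fits"))
  samples <- Reduce(intersect, list(colnames(mrna_B), colnames(mirna_B),
                                    colnames(protein_B)))
  if (length(samples) == 0L) stop("no shared sample IDs", call. = FALSE)
  rows <- lapply(fits, function(f) {
    pid <- f$protein_id
    if (!pid %in% rownames(protein_B)) return(NULL)
    eid <- gene_map$mrna[match(pid, gene_map$protein)]
    if (is.na(eid) || !eid %in% rownames(mrna_B)) return(NULL)
    predict_protein(f, mrna_B[eid, samples],
                    mirna_B[, samples, drop = FALSE],
                    protein_B[pid, samples])$result
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  rownames(out) <- NULL
  out
}

#' Standard scores for an overexpression screen
#'
#' Per protein (antibody), measurements across the whole perturbation screen
#' are converted to standard scores: subtract the screen mean, divide by the
#' screen standard deviation. Effects with `|z| >=` the threshold (default
#' 1.96) are deemed significant.
#'
#' @param raw Numeric matrix, perturbations (miRNAs) x proteins.
#' @param threshold Significance cutoff on `|z|` (default 1.96).
#' @return A list of class `screen_zscores` with `z` (same shape as `raw`)
#'   and `threshold`.
#' @export
screen_zscore <- function(raw, threshold = 1.96) {
  stopifnot(is.matrix(raw))
  if (nrow(raw) < 3L) stop("need >= 3 perturbations per protein",
                           call. = FALSE)
  assert_scalar_number(threshold, "threshold", lower = 0)
  mu <- colMeans(raw, na.rm = TRUE)
  sds <- apply(raw, 2L, stats::sd, na.rm = TRUE)
  if (any(sds == 0 | !is.finite(sds))) {
    stop("zero screen standard deviation for protein(s): ",
         paste(utils::head(colnames(raw)[sds == 0 | !is.finite(sds)], 5L),
               collapse = ", "), call. = FALSE)
  }
  z <- sweep(sweep(raw, 2L, mu), 2L, sds, `/`)
  structure(list(z = z, threshold = threshold), class = "screen_zscores")
}

#' Patient-derived associations consistent with the overexpression screen
#'
#' An association is functionally validated when it is (a) significant in the
#' patient cohort, (b) has `|z| >=` the screen threshold, and (c) the screen
#' effect has the same sign as the fitted coefficient.
#'
#' @param assoc An [association_matrix()].
#' @param z A [screen_zscore()] result; rows are miRNAs, columns proteins.
#' @return Data frame with columns `mirna`, `protein`, `beta`, `z`,
#'   `validated` for all shared significant associations.
#' @export
screen_consistency <- function(assoc, z) {
  stopifnot(inherits(assoc, "association_matrix"),
            inherits(z, "screen_zscores"))
  shared_m <- intersect(colnames(assoc$beta), rownames(z$z))
  shared_p <- intersect(rownames(assoc$beta), colnames(z$z))
  idx <- which(assoc$significant[shared_p, shared_m, drop = FALSE],
               arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(mirna = character(0), protein = character(0),
                      beta = numeric(0), z = numeric(0),
                      validated = logical(0), stringsAsFactors = FALSE))
  }
  prot <- shared_p[idx[, 1L]]
  mir <- shared_m[idx[, 2L]]
  beta <- assoc$beta[cbind(match(prot, rownames(assoc$beta)),
                           match(mir, colnames(assoc$beta)))]
  zz <- z$z[cbind(match(mir, rownames(z$z)), match(prot, colnames(z$z)))]
  out <- data.frame(mirna = mir, protein = prot, beta = beta, z = zz,
                    validated = !is.na(zz) & abs(zz) >= z$threshold &
                      sign(zz) == sign(beta),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}
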