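# Interactome map: two-way clustering of the coefficient table B.
#
# The proteins x miRNAs table of fitted miRNA coefficients is clustered along
# both axes with Pearson-correlation distance and complete linkage; blocks of
# same-sign coefficients spanning a protein cluster and a miRNA cluster are
# the signature of coordinated miRNA action. Flat clusters are obtained by
# cutting each tree at a fixed k (a deliberate substitution for
# dendrogram-partitioning heuristics, whose cluster counts are treated as
# data-dependent observations, not contract). The clustering operates on the
# full coefficient table, significant and nonsignificant cells alike.

#' Pearson correlation distance between matrix rows
#'
#' `d(i, j) = 1 - cor(row_i, row_j)`, in `[0, 2]`. Rows with zero variance
#' have no defined correlation; by the "uncorrelated" convention their
#' distance to every other row is 1 (0 on the diagonal), and they are logged
#' with a warning.
#'
#' @param x Numeric matrix with >= 2 rows.
#' @return Symmetric distance matrix with zero diagonal, dimnames from the
#'   rownames of `x`.
#' @export
correlation_distance <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  sds <- apply(x, 1L, stats::sd)
  flat <- !is.finite(sds) | sds == 0
  d <- matrix(1, nrow(x), nrow(x), dimnames = list(rownames(x), rownames(x)))
  if (any(!flat)) {
    cc <- stats::cor(t(x[!flat, , drop = FALSE]))
    d[!flat, !flat] <- 1 - cc
  }
  if (any(flat)) {
    warning(sprintf("%d zero-variance row(s) assigned distance 1 to all rows",
                    sum(flat)), call. = FALSE)
  }
  diag(d) <- 0
  d
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Complete-linkage agglomeration (other linkages available for
#' completeness). Deterministic for a given input.
#'
#' @param dist_matrix Symmetric numeric distance matrix (zero diagonal) or a
#'   `dist` object.
#' @param linkage Linkage criterion (default `"complete"`).
#' @return An [stats::hclust] tree.
#' @export
hierarchical_cluster <- function(dist_matrix,
                                 linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  if (!inherits(dist_matrix, "dist")) {
    stopifnot(is.matrix(dist_matrix))
    if (!isSymmetric(unname(dist_matrix), tol = 1e-8)) {
      stop("distance matrix must be symmetric", call. = FALSE)
    }
    dist_matrix <- stats::as.dist(dist_matrix)
  }
  stats::hclust(dist_matrix, method = linkage)
}

#' Flat clusters from a merge tree
#'
#' Cuts the tree into exactly `k` clusters.
#'
#' @param tree An [stats::hclust] tree.
#' @param k Number of clusters, `1 <= k <=` number of leaves.
#' @return Integer vector of cluster labels named by leaf.
#' @export
extract_clusters <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n_leaves <- length(tree$order)
  assert_scalar_number(k, "k", lower = 1, upper = n_leaves)
  stats::cutree(tree, k = k)
}

#' Suggest a cluster count by average silhouette width
#'
#' Scans `k = 2..k_max` and returns the k maximizing the mean silhouette
#' width computed directly from the distance matrix. A small utility for
#' choosing the tree-cut defaults; the result is a heuristic, not contract.
#'
#' @param tree An [stats::hclust] tree.
#' @param dist_matrix The distance matrix the tree was built from.
#' @param k_max Largest k to consider.
#' @return The suggested k (integer).
#' @export
suggest_k <- function(tree, dist_matrix, k_max = 10L) {
  if (inherits(dist_matrix, "dist")) dist_matrix <- as.matrix(dist_matrix)
  n <- nrow(dist_matrix)
  k_max <- min(k_max, n - 1L)
  sil_mean <- function(labels) {
    s <- vapply(seq_len(n), function(i) {
      own <- labels == labels[i]
      own[i] <- FALSE
      a <- if (any(own)) mean(dist_matrix[i, own]) else 0
      others <- setdiff(unique(labels), labels[i])
      if (length(others) == 0L) return(0)
      b <- min(vapply(others, function(g) {
        mean(dist_matrix[i, labels == g])
      }, numeric(1L)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1L))
    mean(s)
  }
  scores <- vapply(2:k_max, function(k) sil_mean(extract_clusters(tree, k)),
                   numeric(1L))
  as.integer((2:k_max)[which.max(scores)])
}

#' Two-way clustering of an association matrix
#'
#' Builds the interactome map: proteins (rows) and miRNAs (columns) of the
#' coefficient table are each clustered with correlation distance and
#' complete linkage, then cut at fixed counts.
#'
#' @param assoc An [association_matrix()].
#' @param k_rows,k_cols Number of protein and miRNA clusters.
#' @return A list of class `cluster_assignment`: `row_labels`, `col_labels`,
#'   `row_tree`, `col_tree`.
#' @export
cluster_association <- function(assoc, k_rows, k_cols) {
  stopifnot(inherits(assoc, "association_matrix"))
  B <- assoc$beta
  B[is.na(B)] <- 0
  row_tree <- hierarchical_cluster(correlation_distance(B))
  col_tree <- hierarchical_cluster(correlation_distance(t(B)))
  structure(list(row_labels = extract_clusters(row_tree, k_rows),
                 col_labels = extract_clusters(col_tree, k_cols),
                 row_tree = row_tree, col_tree = col_tree),
            class = "cluster_assignment")
}

#' Export significant associations as a SIF edge list
#'
#' One edge per association passing the filter, in simple interaction format
#' `mirna <TAB> pos|neg <TAB> protein` (Cytoscape-compatible).
#'
#' @param assoc An [association_matrix()].
#' @param min_abs Minimum `|beta|` for an edge (default 0; the cross-cohort
#'   concurrence analysis used 0.15).
#' @param significant_only Keep only cells flagged significant (default
#'   `TRUE`).
#' @param path Optional file to write the SIF lines to.
#' @return Data frame with columns `mirna`, `sign` (`"pos"`/`"neg"`),
#'   `protein`; invisibly when `path` is given.
#' @export
export_network <- function(assoc, min_abs = 0, significant_only = TRUE,
                           path = NULL) {
  stopifnot(inherits(assoc, "association_matrix"))
  assert_scalar_number(min_abs, "min_abs", lower = 0)
  keep <- !is.na(assoc$beta) & abs(assoc$beta) >= min_abs
  if (significant_only) keep <- keep & assoc$significant
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(
    mirna = colnames(assoc$beta)[idx[, 2L]],
    sign = ifelse(assoc$beta[idx] > 0, "pos", "neg"),
    protein = rownames(assoc$beta)[idx[, 1L]],
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$mirna, edges$protein), , drop = FALSE]
  rownames(edges) <- NULL
  if (!is.null(path)) {
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(edges))
  }
  edges
}
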