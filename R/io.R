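# Readers/writers and the end-to-end pipeline.
#
# Matrix dialect: TSV, UTF-8, decimal point; first column the feature ID,
# header row the sample IDs. Run configuration is YAML; the run summary is
# JSON with a content-hash manifest so that reruns can be compared
# bit-for-bit.

#' Read an expression matrix from TSV
#'
#' @param path TSV file (first column feature IDs, header sample IDs).
#' @param level Molecular level of the matrix (default `"protein"`).
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path, level = c("protein", "miRNA", "mRNA")) {
  level <- match.arg(level)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop(path, ": matrix has 0 rows", call. = FALSE)
  if (ncol(df) < 2L) stop(path, ": expected feature column + samples",
                          call. = FALSE)
  feats <- as.character(df[[1L]])
  if (anyDuplicated(feats)) {
    stop(path, ": duplicated feature ID(s): ",
         paste(utils::head(unique(feats[duplicated(feats)]), 5L),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(df)[-1L])) {
    stop(path, ": duplicated sample ID(s) in header", call. = FALSE)
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1L)))[1L]
    stop(sprintf("%s: non-numeric values in column '%s'",
                 path, names(df)[-1L][bad]), call. = FALSE)
  }
  rownames(vals) <- feats
  expression_matrix(vals, level)
}

#' Write an expression matrix to TSV
#'
#' @param matrix Features x samples numeric matrix with dimnames.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(is.matrix(matrix))
  df <- data.frame(feature = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a pipeline run configuration
#'
#' @param protein,mrna,mirna Paths to the three expression TSVs (linear
#'   scale), or in-memory matrices.
#' @param gene_map Path to a protein/mRNA pairing TSV (columns `protein`,
#'   `mrna`) or a data frame.
#' @param out_dir Output directory for all artifacts.
#' @param delta0 Standardization offset (default 0.1).
#' @param target_fdr Screen-wide FDR bound (default 0.01).
#' @param prescreen_alpha Univariate prescreen cutoff (default 0.01).
#' @param cv_folds,cv_seed Lasso cross-validation settings.
#' @param k_rows,k_cols Interactome cluster counts (`NULL`: silhouette
#'   heuristic).
#' @param edge_min_abs Minimum `|beta|` for exported network edges.
#' @param screen_threshold Overexpression-screen z cutoff.
#' @return A list of class `run_config`.
#' @export
run_config <- function(protein, mrna, mirna, gene_map, out_dir,
                       delta0 = 0.1, target_fdr = 0.01,
                       prescreen_alpha = 0.01, cv_folds = 10L, cv_seed = 1L,
                       k_rows = NULL, k_cols = NULL, edge_min_abs = 0,
                       screen_threshold = 1.96) {
  assert_scalar_number(delta0, "delta0", lower = 0, strict_lower = TRUE)
  assert_scalar_number(target_fdr, "target_fdr", lower = 0, upper = 1)
  assert_scalar_number(prescreen_alpha, "prescreen_alpha", lower = 0,
                       upper = 1)
  assert_scalar_number(cv_folds, "cv_folds", lower = 2)
  structure(list(protein = protein, mrna = mrna, mirna = mirna,
                 gene_map = gene_map, out_dir = out_dir, delta0 = delta0,
                 target_fdr = target_fdr, prescreen_alpha = prescreen_alpha,
                 cv_folds = as.integer(cv_folds),
                 cv_seed = as.integer(cv_seed),
                 k_rows = k_rows, k_cols = k_cols,
                 edge_min_abs = edge_min_abs,
                 screen_threshold = screen_threshold),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Write a run configuration to YAML
#'
#' @param config A `run_config`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

resolve_matrix <- function(x, level) {
  if (is.character(x)) read_matrix(x, level) else {
    stopifnot(is.matrix(x)); x
  }
}

resolve_map <- function(x) {
  if (is.character(x)) {
    utils::read.delim(x, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(x)); x
  }
}

#' Run the full association pipeline
#'
#' standardize -> log -> univariate screen -> FDR calls -> prescreened Lasso
#' -> interactome clustering -> network export -> patient scores. All
#' artifacts are written under `config$out_dir`; the summary JSON records the
#' screen bookkeeping (N, S, P*, FDR-hat), per-protein selection counts,
#' seeds, version, and an md5 manifest of every output file. Reruns with the
#' same configuration are bit-identical.
#'
#' @param config A [run_config()].
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  prot_raw <- resolve_matrix(config$protein, "protein")
  mrna_raw <- resolve_matrix(config$mrna, "mRNA")
  mirna_raw <- resolve_matrix(config$mirna, "miRNA")
  gene_map <- resolve_map(config$gene_map)

  std <- stage("standardize", {
    lapply(list(protein = prot_raw, mrna = mrna_raw, mirna = mirna_raw),
           standardize, delta0 = config$delta0)
  })
  logm <- stage("log", lapply(std, function(s) log_transform(s$values)))

  tab <- stage("univariate", {
    fit_all_pairs(logm$protein, logm$mrna, logm$mirna, gene_map)
  })
  assoc <- stage("fdr", call_significant(tab, config$target_fdr))

  fits <- stage("multivariate", {
    fit_all_multivariate(logm$protein, logm$mrna, logm$mirna, gene_map, tab,
                         alpha_level = config$prescreen_alpha,
                         cv_folds = config$cv_folds,
                         cv_seed = config$cv_seed)
  })

  clust <- stage("interactome", {
    B <- assoc$beta; B[is.na(B)] <- 0
    d_rows <- correlation_distance(B)
    d_cols <- correlation_distance(t(B))
    row_tree <- hierarchical_cluster(d_rows)
    col_tree <- hierarchical_cluster(d_cols)
    k_rows <- config$k_rows %||% suggest_k(row_tree, d_rows)
    k_cols <- config$k_cols %||% suggest_k(col_tree, d_cols)
    structure(list(row_labels = extract_clusters(row_tree, k_rows),
                   col_labels = extract_clusters(col_tree, k_cols),
                   row_tree = row_tree, col_tree = col_tree),
              class = "cluster_assignment")
  })

  scores <- stage("scores", compute_scores(fits, logm$mirna))

  stage("write", {
    utils::write.table(
      data.frame(tab, check.names = FALSE),
      file.path(out, "univariate.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      multivariate_coefs(fits), file.path(out, "multivariate.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    export_network(assoc, min_abs = config$edge_min_abs,
                   path = file.path(out, "network.sif"))
    write_matrix(unclass(scores), file.path(out, "scores.tsv"))
    clusters_df <- rbind(
      data.frame(id = names(clust$row_labels), axis = "protein",
                 cluster = as.integer(clust$row_labels)),
      data.frame(id = names(clust$col_labels), axis = "miRNA",
                 cluster = as.integer(clust$col_labels)))
    utils::write.table(clusters_df, file.path(out, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  selected <- vapply(fits, function(f) length(f$beta_hats), integer(1L))
  files <- c("univariate.tsv", "multivariate.tsv", "network.sif",
             "scores.tsv", "clusters.tsv")
  manifest <- lapply(files, function(f) {
    list(file = f,
         md5 = unname(tools::md5sum(file.path(out, f))))
  })
  summary <- list(
    version = as.character(utils::packageVersion("mirprot")),
    n_tests = nrow(tab),
    n_proteins = attr(tab, "n_proteins"),
    n_mirnas = attr(tab, "n_mirnas"),
    fdr = list(N = assoc$fdr$N, p_star = assoc$fdr$p_star, S = assoc$fdr$S,
               fdr_hat = assoc$fdr$fdr_hat,
               target_fdr = config$target_fdr),
    n_significant = sum(assoc$significant),
    n_negative = sum(assoc$sign < 0),
    n_positive = sum(assoc$sign > 0),
    selected_per_protein = as.list(selected),
    delta0 = config$delta0,
    prescreen_alpha = config$prescreen_alpha,
    cv_folds = config$cv_folds,
    cv_seed = config$cv_seed,
    manifest = manifest)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
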