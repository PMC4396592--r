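# Overlap with in silico miRNA target predictions.
#
# Negative significant associations that are independently predicted as
# miRNA-target pairs by at least k of the available algorithms (default
# k = 2 of 3, reflecting the limited accuracy of individual predictors) are
# nominated as putative direct miRNA-mRNA interactions.

#' Load per-algorithm miRNA target-prediction pair lists
#'
#' Each file is a 2-column TSV (`miRNA`, `gene`), one predicted pair per
#' line, with or without a header. Identifiers are case-folded and
#' whitespace-trimmed; duplicate pairs within an algorithm are stored once.
#'
#' @param files Named character vector of file paths; names are the
#'   algorithm names (defaults to the file base names).
#' @return A named list of class `target_db`; each element a data frame with
#'   columns `mirna` and `gene`.
#' @export
load_targets <- function(files) {
  if (is.null(names(files)) || any(names(files) == "")) {
    names(files) <- tools::file_path_sans_ext(basename(files))
  }
  db <- lapply(seq_along(files), function(i) {
    path <- files[[i]]
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      warning("empty target file: ", path, call. = FALSE)
      return(data.frame(mirna = character(0), gene = character(0),
                        stringsAsFactors = FALSE))
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 2L)
    if (length(bad)) {
      stop(sprintf("%s: malformed line %d (expected 2 tab-separated columns)",
                   path, bad[1L]), call. = FALSE)
    }
    mirna <- tolower(trimws(vapply(parts, `[[`, "", 1L)))
    gene <- tolower(trimws(vapply(parts, `[[`, "", 2L)))
    # tolerate a header line
    if (mirna[1L] %in% c("mirna", "mir") && gene[1L] %in% c("gene", "target")) {
      mirna <- mirna[-1L]; gene <- gene[-1L]
    }
    unique(data.frame(mirna = mirna, gene = gene, stringsAsFactors = FALSE))
  })
  structure(stats::setNames(db, names(files)), class = "target_db")
}

#' Putative direct miRNA-mRNA interactions
#'
#' Returns the (miRNA, protein) pairs that are significant with a negative
#' coefficient in the association matrix and whose (miRNA, gene) pair is
#' predicted by at least `min_algorithms` of the loaded algorithms.
#'
#' @param assoc An [association_matrix()].
#' @param db A [load_targets()] database.
#' @param gene_map Data frame with columns `protein` and `gene` (or `mrna`)
#'   aligning protein IDs to the gene IDs used in the prediction lists.
#' @param min_algorithms Minimum number of concurring algorithms (default 2).
#' @return Data frame with columns `mirna`, `protein`, `gene`, `beta`,
#'   `n_algorithms`.
#' @export
putative_direct <- function(assoc, db, gene_map, min_algorithms = 2L) {
  stopifnot(inherits(assoc, "association_matrix"), inherits(db, "target_db"))
  if (min_algorithms > length(db)) {
    stop(sprintf("min_algorithms (%d) exceeds number of algorithms (%d)",
                 min_algorithms, length(db)), call. = FALSE)
  }
  gene_col <- if ("gene" %in% names(gene_map)) "gene" else "mrna"
  neg <- which(assoc$significant & !is.na(assoc$beta) & assoc$beta < 0,
               arr.ind = TRUE)
  if (nrow(neg) == 0L) {
    return(data.frame(mirna = character(0), protein = character(0),
                      gene = character(0), beta = numeric(0),
                      n_algorithms = integer(0), stringsAsFactors = FALSE))
  }
  prot <- rownames(assoc$beta)[neg[, 1L]]
  mir <- colnames(assoc$beta)[neg[, 2L]]
  gene <- gene_map[[gene_col]][match(prot, gene_map$protein)]
  key <- paste(tolower(trimws(mir)), tolower(trimws(gene)), sep = "\r")
  n_alg <- Reduce(`+`, lapply(db, function(d) {
    key %in% paste(d$mirna, d$gene, sep = "\r")
  }))
  keep <- n_alg >= min_algorithms & !is.na(gene)
  out <- data.frame(mirna = mir[keep], protein = prot[keep],
                    gene = gene[keep], beta = assoc$beta[neg][keep],
                    n_algorithms = as.integer(n_alg[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}
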