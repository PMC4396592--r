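# Synthetic multi-omic cohort generator.
#
# Cohorts are drawn from the same power-law model that the fitting modules
# estimate: miRNA and mRNA levels come from configurable positive laws
# (log-normal by default, since the fitted model is linear on the log scale),
# and protein is generated as
#     P = exp(alpha + sum_j beta_j log M_j + gamma log E + eps),
# eps ~ N(0, noise_sd) on the log scale. Optional subtype structure is
# injected as additive offsets on the log-miRNA scale; protein inherits it
# through the model. Ground truth (coefficients, support, labels) travels
# with the matrices so recovery can be scored exactly.

default_law <- function() list(dist = "lognormal", meanlog = 0, sdlog = 1)

draw_law <- function(law, n) {
  dist <- law$dist %||% "lognormal"
  x <- switch(dist,
    lognormal = stats::rlnorm(n, meanlog = law$meanlog %||% 0,
                              sdlog = law$sdlog %||% 1),
    gamma = stats::rgamma(n, shape = law$shape %||% 2,
                          rate = law$rate %||% 1),
    uniform = stats::runif(n, min = law$min %||% 0.5, max = law$max %||% 2),
    stop("unknown generating distribution: ", dist, call. = FALSE)
  )
  if (any(x <= 0)) {
    stop("generating law produced nonpositive values; ",
         "choose a strictly positive law", call. = FALSE)
  }
  x
}

#' Configuration of a synthetic miRNA/mRNA/protein cohort
#'
#' The defaults mirror the structure of the breast-tumor cohort the model was
#' designed for: 283 samples, 105 protein/mRNA pairs and 421 miRNAs.
#'
#' @param n_samples,n_proteins,n_mirnas Cohort dimensions (all >= 1).
#' @param support Per-protein miRNA effects: a list of length `n_proteins`
#'   whose elements are numeric vectors of beta coefficients named by miRNA
#'   *index* (1-based, as character). `NULL` means no miRNA acts on any
#'   protein. See [random_support()].
#' @param gamma Per-protein mRNA exponent (recycled to `n_proteins`).
#' @param alpha Per-protein intercept on the natural-log scale (recycled).
#' @param noise_sd Standard deviation of the Gaussian error on the log scale
#'   (>= 0).
#' @param mirna_law,mrna_law Positive-valued generating laws; a list with a
#'   `dist` field (`"lognormal"`, `"gamma"` or `"uniform"`) plus parameters.
#'   Default: log-normal with meanlog 0, sdlog 1.
#' @param n_subtypes Number of sample subtypes (0 = no block structure).
#' @param subtype_shift Per-subtype mean offsets on the log-miRNA scale:
#'   either a numeric vector of length `n_subtypes` (same offset for every
#'   miRNA) or an `n_subtypes` x `n_mirnas` matrix.
#' @param seed Integer master seed; all per-operation substreams are derived
#'   from it deterministically.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_samples = 283L, n_proteins = 105L,
                              n_mirnas = 421L, support = NULL,
                              gamma = 1, alpha = 0, noise_sd = 0.25,
                              mirna_law = default_law(),
                              mrna_law = default_law(),
                              n_subtypes = 0L, subtype_shift = NULL,
                              seed = 1L) {
  assert_scalar_number(n_samples, "n_samples", lower = 1)
  assert_scalar_number(n_proteins, "n_proteins", lower = 1)
  assert_scalar_number(n_mirnas, "n_mirnas", lower = 1)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(n_subtypes, "n_subtypes", lower = 0)
  assert_scalar_number(seed, "seed", lower = 0,
                       upper = .Machine$integer.max)
  if (is.null(support)) support <- vector("list", n_proteins)
  if (length(support) != n_proteins) {
    stop("`support` must have one element per protein", call. = FALSE)
  }
  for (s in support) {
    if (is.null(s) || length(s) == 0L) next
    idx <- as.integer(names(s))
    if (anyNA(idx) || any(idx < 1L) || any(idx > n_mirnas)) {
      stop("support indices must name miRNA indices in 1..n_mirnas",
           call. = FALSE)
    }
  }
  if (n_subtypes > 0L) {
    if (is.null(subtype_shift)) subtype_shift <- seq_len(n_subtypes) - 1
    if (is.matrix(subtype_shift)) {
      stopifnot(nrow(subtype_shift) == n_subtypes,
                ncol(subtype_shift) == n_mirnas)
    } else {
      stopifnot(length(subtype_shift) == n_subtypes)
    }
  }
  structure(list(
    n_samples = as.integer(n_samples), n_proteins = as.integer(n_proteins),
    n_mirnas = as.integer(n_mirnas), support = support,
    gamma = rep_len(gamma, n_proteins), alpha = rep_len(alpha, n_proteins),
    noise_sd = noise_sd, mirna_law = mirna_law, mrna_law = mrna_law,
    n_subtypes = as.integer(n_subtypes), subtype_shift = subtype_shift,
    seed = as.integer(seed)), class = "sim_config")
}

#' Draw a random sparse support set for the simulator
#'
#' Assigns each protein `k` regulating miRNAs chosen uniformly without
#' replacement, with coefficients sampled from `betas`.
#'
#' @param n_proteins,n_mirnas Cohort dimensions.
#' @param k Number of nonzero miRNA effects per protein.
#' @param betas Pool of coefficient values to sample from.
#' @param seed Integer seed.
#' @return A support list suitable for [simulation_config()].
#' @export
random_support <- function(n_proteins, n_mirnas, k,
                           betas = c(-1, -0.5, 0.5, 1), seed = 1L) {
  stopifnot(k <= n_mirnas)
  with_seed(seed, lapply(seq_len(n_proteins), function(i) {
    idx <- sort(sample.int(n_mirnas, k))
    stats::setNames(sample(betas, k, replace = TRUE), as.character(idx))
  }))
}

# Dense n_proteins x n_mirnas coefficient matrix from a support list.
support_to_matrix <- function(config) {
  B <- matrix(0, config$n_proteins, config$n_mirnas)
  for (i in seq_len(config$n_proteins)) {
    s <- config$support[[i]]
    if (length(s)) B[i, as.integer(names(s))] <- s
  }
  B
}

#' Simulate a coupled miRNA/mRNA/protein cohort with known ground truth
#'
#' @param config A [simulation_config()].
#' @return A list of class `sim_cohort` with components `mirna`, `mrna`,
#'   `protein` (each an [expression_matrix()], features x samples) and
#'   `truth`, a list carrying the config, the dense coefficient matrix
#'   `beta`, the `gamma` and `alpha` vectors, `noise_sd` and the per-sample
#'   `subtype` labels (`NULL` when `n_subtypes == 0`). Identical seeds give
#'   bit-identical output.
#' @examples
#' cfg <- simulation_config(n_samples = 20, n_proteins = 3, n_mirnas = 10,
#'                          seed = 7)
#' coh <- simulate_cohort(cfg)
#' dim(coh$protein)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, 4L)
  ns <- config$n_samples; np <- config$n_proteins; nm <- config$n_mirnas

  sample_ids <- sprintf("sample_%03d", seq_len(ns))
  mirna_ids <- sprintf("mir_%04d", seq_len(nm))
  gene_ids <- sprintf("gene_%03d", seq_len(np))
  prot_ids <- sprintf("prot_%03d", seq_len(np))

  M <- with_seed(seeds[1L],
                 matrix(draw_law(config$mirna_law, nm * ns), nm, ns))
  E <- with_seed(seeds[2L],
                 matrix(draw_law(config$mrna_law, np * ns), np, ns))

  subtype <- NULL
  if (config$n_subtypes > 0L) {
    subtype <- with_seed(seeds[3L],
                         sample.int(config$n_subtypes, ns, replace = TRUE))
    shift <- config$subtype_shift
    if (!is.matrix(shift)) {
      shift <- matrix(shift, config$n_subtypes, nm)
    }
    # additive on the log scale = multiplicative on the raw scale
    M <- M * exp(t(shift)[, subtype, drop = FALSE])
  }

  B <- support_to_matrix(config)
  logP <- config$alpha + B %*% log(M) + config$gamma * log(E)
  if (config$noise_sd > 0) {
    eps <- with_seed(seeds[4L],
                     matrix(stats::rnorm(np * ns, sd = config$noise_sd),
                            np, ns))
    logP <- logP + eps
  }
  P <- exp(logP)
  if (any(!is.finite(P)) || any(P <= 0)) {
    stop("simulation produced nonpositive or nonfinite protein values",
         call. = FALSE)
  }

  dimnames(M) <- list(mirna_ids, sample_ids)
  dimnames(E) <- list(gene_ids, sample_ids)
  dimnames(P) <- list(prot_ids, sample_ids)
  rownames(B) <- prot_ids
  colnames(B) <- mirna_ids

  truth <- list(config = config, beta = B, gamma = config$gamma,
                alpha = config$alpha, noise_sd = config$noise_sd,
                subtype = subtype)
  structure(list(
    mirna = expression_matrix(M, "miRNA"),
    mrna = expression_matrix(E, "mRNA"),
    protein = expression_matrix(P, "protein"),
    gene_map = data.frame(protein = prot_ids, mrna = gene_ids,
                          stringsAsFactors = FALSE),
    truth = truth), class = "sim_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits the three expression matrices as TSV (first column the feature ID,
#' header row the sample IDs), the protein-to-mRNA pairing as TSV, and the
#' ground truth as JSON.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mirna = file.path(dir, "mirna.tsv"),
             mrna = file.path(dir, "mrna.tsv"),
             protein = file.path(dir, "protein.tsv"),
             gene_map = file.path(dir, "gene_map.tsv"),
             truth = file.path(dir, "truth.json"))
  write_matrix(cohort$mirna, paths[["mirna"]])
  write_matrix(cohort$mrna, paths[["mrna"]])
  write_matrix(cohort$protein, paths[["protein"]])
  utils::write.table(cohort$gene_map, paths[["gene_map"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth_json <- list(
    n_samples = truth$config$n_samples,
    n_proteins = truth$config$n_proteins,
    n_mirnas = truth$config$n_mirnas,
    seed = truth$config$seed,
    noise_sd = truth$noise_sd,
    alpha = truth$alpha, gamma = truth$gamma,
    support = lapply(truth$config$support, function(s) as.list(s)),
    subtype = truth$subtype)
  jsonlite::write_json(truth_json, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
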