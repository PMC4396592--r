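# Small cohort fixtures built in code.

toy_cohort <- function(n_samples = 40, n_proteins = 2, n_mirnas = 3,
                       noise_sd = 0, seed = 101, ...) {
  simulate_cohort(simulation_config(
    n_samples = n_samples, n_proteins = n_proteins, n_mirnas = n_mirnas,
    noise_sd = noise_sd, seed = seed, ...))
}

# Log-transformed matrices of a cohort (no standardization: the generative
# model is exactly linear on the raw log scale).
cohort_logs <- function(cohort) {
  list(protein = log_transform(cohort$protein),
       mrna = log_transform(cohort$mrna),
       mirna = log_transform(cohort$mirna))
}

random_expr <- function(nr, nc, seed = 1, prefix = "f") {
  set.seed(seed)
  m <- matrix(stats::rlnorm(nr * nc), nr, nc,
              dimnames = list(sprintf("%s%02d", prefix, seq_len(nr)),
                              sprintf("s%02d", seq_len(nc))))
  m
}
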