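# Fixtures are generated in code; no data files.

# Additive (rank-1 in the centred sense) matrix: x_ij = center + u_i + v_j + noise
rank1_qm <- function(n = 100, m = 20, noise_sd = 0.1, center = 12, seed = 1) {
  vals <- lupine:::with_seed(seed, {
    u <- rnorm(n)
    v <- rnorm(m)
    center + outer(u, rep(1, m)) + outer(rep(1, n), v) +
      matrix(rnorm(n * m, 0, noise_sd), n)
  })
  dimnames(vals) <- list(sprintf("P%04d", seq_len(n)),
                         sprintf("S%03d", seq_len(m)))
  quant_matrix(vals)
}

random_qm <- function(n = 20, m = 10, miss_frac = 0.2, mean = 0, sd = 1,
                      seed = 1) {
  vals <- lupine:::with_seed(seed, {
    v <- matrix(rnorm(n * m, mean, sd), n)
    if (miss_frac > 0) {
      v[sample(length(v), round(miss_frac * length(v)))] <- NA
    }
    v
  })
  dimnames(vals) <- list(sprintf("P%04d", seq_len(n)),
                         sprintf("S%03d", seq_len(m)))
  quant_matrix(vals)
}

# Tiny hyperparameter settings that train in well under a second
tiny_hp <- function(...) {
  hyperparams(n_protein_factors = 8, n_sample_factors = 8,
              n_hidden_layers = 1, nodes_per_layer = 32, ...)
}

# Hide test-labelled entries so baseline imputers cannot see them
hide_test_entries <- function(X, mask) {
  v <- X$values
  v[mask_entries(mask, "test")] <- NA
  quant_matrix(v, X$dataset)
}
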