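# shared fixtures, generated in code at test time

# small dense expression matrix with deterministic values
tiny_expression <- function(n = 4, d = 3, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(round(rnorm(n * d, 5, 2), 3), n, d,
                dimnames = list(sprintf("c%d", 1:n), sprintf("g%d", 1:d)))
  })
  expression_matrix(m)
}

# well-separated clustered dataset for quick training checks
separable_dataset <- function(n = 300, d = 60, k = 3, seed = 7,
                              separation = 5) {
  generate_dataset(synthetic_spec(n, d, k, latent_dim = 8,
                                  separation = separation, noise_sd = 1,
                                  dropout_rate = 0.1, seed = seed))
}

# desk-scale pipeline configuration used across integration tests
small_pipeline_config <- function(seed = 3) {
  pipeline_config(hidden_widths = c(32, 16), classifier_hidden = c(16, 8),
                  fast = TRUE, seed = seed)
}

# subset an expression matrix by cell indices, preserving the class
subset_cells <- function(x, idx) {
  expression_matrix(unclass(x)[idx, , drop = FALSE],
                    standardized = is_standardized(x))
}

subset_labels <- function(labels, idx) {
  label_set(labels$cell_ids[idx], labels$labels[idx])
}
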