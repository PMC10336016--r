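# Small fixtures shared across tests; everything is generated in code.

tiny_spec <- function(n = 120, seed = 3, ...) {
  cohort_spec(n_subjects = n, seed = seed, ...)
}

tiny_design <- function(n = 120, seed = 3, ...) {
  tab <- generate_cohort(tiny_spec(n, seed, ...))
  build_design_matrices(tab, default_schema(tab))
}

tiny_model_config <- function(...) {
  model_config(widths = c(6L), fc_widths = c(4L), degree = 2L, dropout = 0.2, ...)
}

tiny_control <- function(epochs = 15L, lr = 5e-3, ...) {
  train_control(lr = lr, epochs = epochs, patience = epochs, ...)
}

# Random survival batch with at least one event and distinct times.
random_records <- function(n, seed) {
  withr::with_seed(seed, {
    list(risk = stats::rnorm(n),
         time = sample(seq_len(10 * n), n),
         event = c(1L, stats::rbinom(n - 1L, 1L, 0.6)))
  })
}

# Random polynomial-attention parameters (nonzero attention weights, unlike
# the trained initialization, to probe the general case).
random_subnet <- function(d_in, d_out, degree, seed) {
  withr::with_seed(seed, {
    poly_attention_params(
      W_Z = matrix(stats::rnorm(d_out * d_in, sd = 0.5), d_out, d_in),
      b_Z = stats::rnorm(d_out, sd = 0.2),
      w = lapply(seq_len(degree), function(k) {
        matrix(stats::rnorm(d_out * d_out, sd = 0.4 / k), d_out, d_out)
      }),
      b = stats::rnorm(d_out, sd = 0.2)
    )
  })
}
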