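# Shared fixtures: small synthetic datasets and fast training protocols.
# Everything is generated in code under fixed seeds; no files on disk.

# Small, quickly trainable dataset: 60 bags, 8 features, strong signal.
small_bags <- function(seed = 101, n = 60, p = 8, signal = 1.5,
                       positive_fraction = 0.5) {
  generate_synthetic(synthetic_spec(
    n_bags = n, positive_fraction = positive_fraction, p = p,
    signal_shift = signal, seed = seed))
}

small_model_config <- function(p = 8, ...) {
  minn_config(p = p, n_blocks = 2, scorer_hidden = p, ...)
}

fast_train_config <- function(seed = 7, epochs = 15, ...) {
  train_config(epochs = epochs, seed = seed, ...)
}

# A random-weight (untrained) model for forward-pass property tests.
random_model <- function(seed, p = 8, m_star = 12, ...) {
  minn_init(small_model_config(p = p, m_star = m_star, ...), seed = seed)
}

# One random bag with m instances.
random_bag <- function(seed, m = 10, p = 8, label = 1) {
  set.seed(seed)
  bag(matrix(rnorm(m * p), m, p), label = label,
      bag_id = paste0("rb", seed))
}
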