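# Shared fixtures, built in code at test time.

# a well-separated blob dataset (class centers (0.3, 1.0) / (1.0, 0.3))
separable_blobs <- function(seed = 11L) make_blobs(0.3, 1.0, 0.3, seed = seed)

# random nonzero feature vector in [0, 1]^f
rand_features <- function(f) {
  repeat {
    x <- stats::runif(f)
    if (sum(x) > 0) return(x)
  }
}

# ensemble-cosine configurations (d <= 3) whose circuits fit in `max_width`
# qubits; Haar variants restricted to the backend's dense-matrix budget
simulable_qec_grid <- function(max_width = 16L) {
  g <- rbind(cbind(qec_parameter_grid("swap"), variant = "swap"),
             cbind(qec_parameter_grid("haar"), variant = "haar"))
  g <- g[g$width <= max_width, ]
  keep <- g$variant == "swap" |
    g$n_train * log2(sapply(g$n_feature, function(f) max(2, 2^ceiling(log2(f))))) <= 12
  g[keep, ]
}

# one random labeled instance for a config
random_qec_instance <- function(cfg) {
  list(X = matrix(rand_features(cfg$n_feature * cfg$n_train),
                  nrow = cfg$n_train),
       y = sample(c(0L, 1L), cfg$n_train, replace = TRUE),
       x_test = rand_features(cfg$n_feature))
}
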