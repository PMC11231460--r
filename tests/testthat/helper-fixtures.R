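# Small cohorts for unit tests: 60 s at 25 Hz keeps every stage fast while
# leaving ~0.017 Hz spectral resolution, enough to separate the model
# components.
small_spec <- function(n_per_class = 4, effect_size = 2, noise_sd = 0.1,
                       seed = 1L, n_long = 20L, n_short = 2L) {
  cohort_spec(n_per_class = n_per_class, n_long_channels = n_long,
              n_short_channels = n_short, duration_s = 60,
              effect_channels = seq_len(min(5L, n_long)),
              effect_size = effect_size, noise_sd = noise_sd, seed = seed)
}

small_cohort <- function(...) generate_cohort(small_spec(...))

# Planted two-class matrix: `n_inf` informative columns shifted by `effect`
# between classes among pure-noise columns. Labels balanced.
planted_matrix <- function(n = 40, d = 20, n_inf = 1, effect = 2,
                           seed = 1L) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), each = n / 2)
    X <- matrix(rnorm(n * d), n, d)
    for (j in seq_len(n_inf))
      X[, j] <- X[, j] + effect * (y - 0.5)
    colnames(X) <- sprintf("f%03d", seq_len(d))
    list(X = X, y = y, informative = seq_len(n_inf))
  })
}

# Additively separable ("modular") set-function evaluator: fitness of a mask
# is the sum of per-feature weights, affinely mapped so the empty set scores
# 0. Its unique optimum is the set of positive-weight features, which makes
# it an analytic oracle for greedy and exhaustive search.
modular_evaluator <- function(weights) {
  function(mask) {
    if (is.logical(mask)) mask <- which(mask)
    if (!length(mask)) return(0)
    sum(weights[mask])
  }
}
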