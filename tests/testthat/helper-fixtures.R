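# Small, fast fixtures shared across test files. Everything is generated in
# code; no data files.

# A 6-bin custom scheme spanning the intensity axis.
small_scheme <- function() {
  bin_scheme(name = "mini", edges = c(0, 100, 250, 500, 1000, 4000))
}

# A compact synthetic config for structural tests (not the study defaults).
small_config <- function(n = 150, seed = 1, effect = NULL, noise_sd = 1,
                         ...) {
  synthetic_config(n_participants = n, scheme = small_scheme(),
                   effect_vector = effect, noise_sd = noise_sd,
                   seed = seed, ...)
}

# Random strictly positive compositions for property tests.
random_compositions <- function(n, d, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rexp(n * d) + 1e-3, n, d)
  })
  m / rowSums(m)
}

# A daily wear pattern: constant-level wear block, non-wear elsewhere.
one_block_day <- function(start = 8, end = 18, level = 50) {
  data.frame(start = c(0, start, end), end = c(start, end, 24),
             level = c(0, level, 0), wear = c(FALSE, TRUE, FALSE))
}
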