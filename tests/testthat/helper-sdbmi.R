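# Shared fixtures: all synthetic, built in code at test time.

# Small, fast generator settings for unit tests (not the study conditions).
tiny_params <- function(seed = 1L, n_units = 4L, n_trials = 8L, ...) {
  sim_params(n_units = n_units, n_trials_per_stimulus = n_trials,
             seed = seed, ...)
}

# A tiny trial record built by hand.
hand_trial <- function(spikes, stimulus = 1L) {
  list(stimulus = as.integer(stimulus), trial = 1L, spikes = spikes)
}

# Gaussian 4-class toy dataset with well-separated means.
toy_clusters <- function(n_per_class = 20, dim = 6, sep = 10, sd = 1,
                         seed = 42) {
  set.seed(seed)
  mu <- matrix(rnorm(4 * dim), 4, dim) * sep
  labels <- rep(1:4, each = n_per_class)
  x <- mu[labels, ] + matrix(rnorm(4 * n_per_class * dim, sd = sd),
                             4 * n_per_class, dim)
  list(x = x, labels = labels, mu = mu)
}

# Raw confusion-matrix information by literal double sum (independent of
# the package implementation).
mi_bruteforce <- function(q, priors = rep(0.25, ncol(q))) {
  marg <- as.numeric(q %*% priors)
  total <- 0
  for (d in seq_len(nrow(q))) for (i in seq_len(ncol(q))) {
    p <- priors[i] * q[d, i]
    if (p > 0 && marg[d] > 0) total <- total + p * log2(q[d, i] / marg[d])
  }
  total
}

# Decoder stubs for closed-loop tests: functions trial -> length-4 P~.
ideal_stub <- function(trial) {
  p <- numeric(4); p[trial$stimulus] <- 1; p
}
antipodal_stub <- function(trial) {
  p <- numeric(4); p[((trial$stimulus + 1L) %% 4L) + 1L] <- 1; p
}
uniform_stub <- function(trial) rep(0.25, 4)

# Seed-scoped evaluation that restores the caller's RNG state.
with_seed_local <- function(seed, expr) sdbmi:::with_seed(seed, expr)
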