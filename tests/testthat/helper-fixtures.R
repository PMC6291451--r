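# shared fixtures, built in code at test time

# the study's default lag structure
study_lags <- function() lag_spec()

# a small lag structure that keeps toy simulations cheap
tiny_lags <- function() lag_spec(d1 = 1, d2 = 2, n1 = 1, n2 = 1, ny = 2)

# one noiseless synthetic participant at reduced trial length
tiny_experiment <- function(seed = 11, n_trials = 3, duration = 8,
                            snr_db = Inf, ...) {
  cfg <- experiment_config(n_participants = 1, n_trials = n_trials,
                           trial_duration = duration, noise_snr_db = snr_db,
                           ...)
  make_experiment(cfg, seed = seed)
}

# simulate a toy scalar NARX system y(k) = 0.5 y(k-1) + 0.8 u(k-1) and
# return signals shaped for build_regressors (u enters as the position
# channel; the velocity channel is zeroed, and its candidate terms collapse
# to zero norm)
toy_narx <- function(n = 520, seed = 3) {
  set.seed(seed)
  u <- runif(n, -1, 1)
  y <- numeric(n)
  for (k in 2:n) y[k] <- 0.5 * y[k - 1] + 0.8 * u[k - 1]
  list(u = u, y = y)
}

# quick training schedule for unit tests
quick_train <- function(seed = 5, iters = 300, restarts = 2) {
  train_config(max_iterations = iters, restarts = restarts, seed = seed)
}
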