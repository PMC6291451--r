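test_that("free-run generation is seeded and reproducible", {
  par <- draw_hnn_params(lag_spec(), seed = 41)
  spc <- multisine_spec(phases = make_phase_set(41, 1)[[1]])
  a <- simulate_ground_truth(par, spc, duration = 4, noise = noise_spec(12, seed = 7))
  b <- simulate_ground_truth(par, spc, duration = 4, noise = noise_spec(12, seed = 7))
  expect_identical(a$y$samples, b$y$samples)
  d <- simulate_ground_truth(par, spc, duration = 4, noise = noise_spec(12, seed = 8))
  expect_false(identical(a$y$samples, d$y$samples))
})

test_that("with zero feedback the noiseless output is exactly periodic after the transient", {
  par <- draw_hnn_params(lag_spec(), seed = 43)
  par$weights_y <- numeric(5)
  spc <- multisine_spec(phases = make_phase_set(43, 1)[[1]])
  sim <- simulate_ground_truth(par, spc, duration = 4, noise = noise_spec(Inf))
  y <- sim$y$samples
  # without feedback, y(k) is a static map of input lags, and inputs repeat
  # every 256 samples; only the zero-initialized burn-in differs
  fi <- burn_in(par$lags)
  k <- (fi + 1):(length(y) - 256)
  expect_equal(y[k], y[k + 256], tolerance = 1e-13)
})

test_that("segmentation yields the documented period counts", {
  spc <- multisine_spec(phases = rep(0, 10))
  mk <- function(dur) nh_signal(make_multisine(spc, dur)$samples, 256, "rad")
  expect_identical(nrow(segment_signal(mk(36), trim = 3, period = 1)), 30L)
  expect_identical(nrow(segment_signal(mk(7), trim = 3, period = 1)), 1L)
  expect_error(segment_signal(mk(6), trim = 3, period = 1), "too short")
})

test_that("a 7-trial, 36-s trial set segments into 210 aligned periods", {
  par <- draw_hnn_params(lag_spec(), seed = 47)
  phases <- make_phase_set(47, 7)
  trials <- lapply(phases, function(ph) {
    sim <- simulate_ground_truth(par, multisine_spec(phases = ph),
                                 duration = 36, noise = noise_spec(Inf))
    list(p = sim$p, v = sim$v, y = sim$y)
  })
  ts <- trial_set("seg", trials, rate = 256)
  segs <- segment_trials(ts, trim = 3, period = 1)
  expect_identical(sum(vapply(segs, function(s) nrow(s$y), integer(1))), 210L)
  expect_identical(ncol(segs[[1]]$p), 256L)
  # boundaries are stimulus-aligned: every p period is (near-)identical
  expect_lt(max(abs(sweep(segs[[1]]$p, 2, colMeans(segs[[1]]$p)))), 1e-12)
})

test_that("periodicity SNR is +Inf for pure periodic signals and scale-invariant", {
  per <- matrix(rep(sin(2 * pi * (0:63) / 64), 5), nrow = 5, byrow = TRUE)
  expect_identical(estimate_snr(per), Inf)
  set.seed(2)
  noisy <- per + matrix(rnorm(5 * 64, sd = 0.3), 5)
  expect_equal(estimate_snr(noisy), estimate_snr(noisy * 10),
               tolerance = 1e-12)
  expect_equal(estimate_snr(noisy), estimate_snr(noisy * 1e-4),
               tolerance = 1e-9)
  expect_error(estimate_snr(per[1, , drop = FALSE]), "at least 2")
})

test_that("periodicity SNR of white noise matches the analytic expectation and falls with period count", {
  # for m periods of pure white noise the expected variance ratio is
  # 1/(m - 1), i.e. SNR ~ -10 log10(m - 1)
  mc <- function(m, nrep = 300) {
    mean(vapply(seq_len(nrep), function(i) {
      set.seed(1000 + i)
      10^(estimate_snr(matrix(rnorm(m * 64), m)) / 10)
    }, numeric(1)))
  }
  expect_equal(mc(4), 1 / 3, tolerance = 0.1)
  expect_equal(mc(16), 1 / 15, tolerance = 0.1)
  expect_lt(mc(16), mc(4))
})

test_that("periodicity SNR increases with generator SNR, and picks the right channel", {
  par <- draw_hnn_params(lag_spec(), seed = 53)
  spc <- multisine_spec(phases = make_phase_set(53, 1)[[1]])
  est <- sapply(1:20, function(s) {
    vapply(c(0, 10, 20), function(snr) {
      sim <- simulate_ground_truth(par, spc, duration = 8,
                                   noise = noise_spec(snr, seed = s))
      estimate_snr(segment_signal(sim$y, trim = 1, period = 1))
    }, numeric(1))
  })
  expect_true(all(est[2, ] > est[1, ]))
  expect_true(all(est[3, ] > est[2, ]))
  # output selection: the periodic-response channel beats a noise channel
  sim <- simulate_ground_truth(par, spc, duration = 8,
                               noise = noise_spec(15, seed = 3))
  set.seed(4)
  chans <- list(resp = segment_signal(sim$y, 1, 1),
                noise = matrix(rnorm(6 * 256), 6))
  expect_identical(as.character(select_output(chans)), "resp")
})

test_that("experiment generation respects counts, seeds, and records the truth", {
  cfg <- experiment_config(n_participants = 2, n_trials = 3,
                           trial_duration = 7, noise_snr_db = 15)
  exp1 <- make_experiment(cfg, seed = 5)
  expect_length(exp1$participants, 2)
  expect_length(exp1$participants[[1]]$trials, 3)
  expect_length(exp1$truth, 2)
  segs <- segment_trials(exp1$participants[[1]], trim = 3, period = 1)
  expect_identical(sum(vapply(segs, function(s) nrow(s$y), integer(1))),
                   3L * (7L - 6L))
  # manifest carries per-participant seeds and flattened truth parameters
  expect_true(all(c("participant_1_seed", "participant_2_truth")
                  %in% names(exp1$manifest)))
  expect_length(exp1$manifest$participant_1_truth, 19)
  expect_equal(exp1$manifest$participant_1_truth,
               narmaxhnn:::flatten_params(exp1$truth[[1]]))
  # same seed: identical experiment; different seed: different draws
  exp2 <- make_experiment(cfg, seed = 5)
  expect_identical(exp1$manifest, exp2$manifest)
  expect_identical(exp1$participants[[1]]$trials[[2]]$y$samples,
                   exp2$participants[[1]]$trials[[2]]$y$samples)
  exp3 <- make_experiment(cfg, seed = 6)
  expect_false(identical(exp1$manifest, exp3$manifest))
})

test_that("default experiment configuration states the study conditions", {
  cfg <- experiment_config()
  expect_identical(cfg$n_participants, 10L)
  expect_identical(cfg$n_trials, 7L)
  expect_equal(cfg$trial_duration, 36)
  expect_equal(cfg$rate, 256)
  expect_equal(cfg$rms, 0.02)
  expect_equal(cfg$frequencies, c(1, 3, 5, 7, 9, 11, 13, 15, 19, 23))
  expect_equal(cfg$trim, 3)
  expect_identical(lag_spec(cfg$d1, cfg$d2, cfg$n1, cfg$n2, cfg$ny),
                   lag_spec())
})

test_that("ground-truth draws stay inside the stability box and produce bounded output", {
  for (s in 1:8) {
    par <- draw_hnn_params(lag_spec(), seed = 300 + s)
    expect_lt(sum(abs(par$weights_y)), 1.2)
    expect_gte(par$weights_y[1], 0.6)
    sim <- simulate_ground_truth(
      par, multisine_spec(phases = make_phase_set(s, 1)[[1]]),
      duration = 4, noise = noise_spec(Inf))
    expect_true(all(abs(sim$y$samples) <= 1))
    expect_gt(sd(sim$y$samples), 0)
  }
})
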