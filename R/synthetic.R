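#' Output-noise specification for synthetic experiments
#'
#' Additive noise on the generated output at a stated signal-to-noise ratio
#' (in dB, relative to the noiseless output's variance). `snr_db = Inf`
#' means noiseless. `"one_over_f"` noise has power density proportional to
#' 1/f, emulating the colored background of electrophysiological recordings;
#' `"white"` is flat.
#'
#' Injection site: `"process"` (default) adds the noise inside the
#' recursion — each noisy output feeds back into later outputs, which is how
#' the noise terms enter the nonlinear autoregressive model family this
#' package fits (the moving-average part of NARMAX). `"measurement"` adds
#' noise to the record only, after a clean free run. Process noise makes the
#' recent output lags genuinely informative, so multi-step prediction
#' degrades with horizon and input-only models lose the recirculated
#' variance — the qualitative regime the model comparison probes.
#'
#' @param snr_db signal-to-noise ratio in dB (finite or `Inf`).
#' @param color `"white"` or `"one_over_f"`.
#' @param seed RNG seed recorded with the noise draw.
#' @param injection `"process"` or `"measurement"`.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(snr_db = 10, color = c("white", "one_over_f"),
                       seed = 0L, injection = c("process", "measurement")) {
  color <- match.arg(color)
  injection <- match.arg(injection)
  if (is.na(snr_db)) stop("snr_db must be a number or Inf")
  structure(list(snr_db = snr_db, color = color, seed = as.integer(seed),
                 injection = injection),
            class = "noise_spec")
}

# draw a noise series with unit variance and the requested color
draw_noise <- function(n, color, seed) {
  local_seed(seed, {
    e <- stats::rnorm(n)
    if (color == "one_over_f") {
      E <- stats::fft(e)
      f <- c(1, seq_len(n - 1))                  # avoid dividing DC by 0
      f <- pmin(f, n - f + 1)                    # symmetric over Nyquist
      E <- E / sqrt(f)
      e <- Re(stats::fft(E, inverse = TRUE)) / n
    }
    e / stats::sd(e)
  })
}

#' Simulate a ground-truth trial from a known network
#'
#' Free-run generation: the position stimulus and its analytic velocity are
#' produced from the multisine design, range-normalized, and fed through the
#' hierarchical network, which uses its *own* past outputs as the feedback
#' lags (initial outputs seeded at 0). Additive output noise at the stated
#' SNR is injected inside the recursion (process noise, the default) or
#' added to the record afterwards, per the [noise_spec()]. Because one-step
#' fitting later uses measured output lags, free-run generation makes
#' parameter recovery a well-posed identification problem.
#'
#' @param params ground-truth [hnn_params()].
#' @param stimulus a [multisine_spec()] (its phases set the trial's
#'   realization).
#' @param duration trial length in seconds.
#' @param noise a [noise_spec()].
#' @param input_norm optional list with `norm_spec`s `p` and `v` shared
#'   across trials of one participant; fitted on this trial when `NULL`.
#' @return List: `p` (rad), `v` (rad/s), `y` (generator output, noisy),
#'   `y_clean`, and the `input_norm` used.
#' @export
simulate_ground_truth <- function(params, stimulus, duration = 36,
                                  noise = noise_spec(Inf),
                                  input_norm = NULL) {
  stopifnot(inherits(params, "hnn_params"), inherits(stimulus, "multisine_spec"))
  p <- make_multisine(stimulus, duration)
  v <- derive_velocity(stimulus, duration)
  if (is.null(input_norm))
    input_norm <- list(p = fit_normalization(p), v = fit_normalization(v))
  pn <- apply_normalization(p$samples, input_norm$p)
  vn <- apply_normalization(v$samples, input_norm$v)
  y_clean <- free_run_hnn(params, pn, vn)
  y <- y_clean
  if (is.finite(noise$snr_db)) {
    e <- draw_noise(length(y_clean), noise$color, noise$seed)
    # noise scale calibrated against the clean free run
    sigma <- stats::sd(y_clean) * 10^(-noise$snr_db / 20)
    if (noise$injection == "process") {
      y <- free_run_hnn(params, pn, vn, e = sigma * e)
    } else {
      y <- y_clean + sigma * e
    }
  }
  list(p = p, v = v,
       y = nh_signal(y, rate = stimulus$rate, units = "a.u."),
       y_clean = nh_signal(y_clean, rate = stimulus$rate, units = "a.u."),
       input_norm = input_norm)
}

# recursive free run of the network over normalized inputs; returns the
# output series (first burn_in samples are the zero initial condition).
# e, if given, is an innovation series added inside the loop (process
# noise): each noisy output re-enters through the feedback lags.
free_run_hnn <- function(params, pn, vn, e = NULL) {
  lags <- params$lags
  fi <- burn_in(lags)
  n <- length(pn)
  if (n <= fi) stop("inputs shorter than the lag burn-in")
  # node A and B drives depend only on inputs: vectorize them up front
  j1 <- 0:lags$n1; j2 <- 0:lags$n2
  ks <- (fi + 1L):n
  XA <- cbind(vapply(j1, function(j) vn[ks - lags$d1 - j], numeric(length(ks))),
              vapply(j1, function(j) pn[ks - lags$d1 - j], numeric(length(ks))))
  XB <- vapply(j2, function(j) pn[ks - lags$d2 - j], numeric(length(ks)))
  if (is.null(dim(XB))) XB <- matrix(XB, nrow = length(ks))
  preA <- params$bias_A + as.numeric(XA %*% params$weights_A)
  preB <- params$bias_B + as.numeric(XB %*% params$weights_B)
  outA <- node_output_map(hnn_sigmoid(preA, params$sigmoid_1), params$sigmoid_1)
  outB <- node_output_map(hnn_sigmoid(preB, params$sigmoid_1), params$sigmoid_1)
  drive <- params$bias_C + params$weight_AC * outA + params$weight_BC * outB
  y <- numeric(n)                          # initial ny (and burn-in) outputs 0
  wy <- params$weights_y
  ny <- lags$ny
  s2 <- params$sigmoid_2
  c2 <- sigmoid_floor(s2)
  for (i in seq_along(ks)) {
    k <- ks[i]
    preC <- drive[i] + sum(wy * y[k - seq_len(ny)])
    # node_output_map(hnn_sigmoid(preC, s2), s2) inlined for the hot loop
    y[k] <- 2 * stats::plogis(s2$rho * (preC - s2$w)) - 1
    if (!is.null(e)) y[k] <- y[k] + e[k]
    if (abs(y[k]) > 1e3)
      stop("free-run output diverged (|y| > 1e3) for this parameter set")
  }
  y
}

#' Segment a trial into stimulus-aligned periods
#'
#' Removes `trim` seconds from each end of the trial (transient suppression)
#' and splits the remainder into consecutive `period`-second segments
#' aligned to the stimulus period. A 36-s trial trimmed by 3 s yields 30
#' one-second periods.
#'
#' @param x an [nh_signal()].
#' @param trim seconds removed at each end.
#' @param period segment length in seconds.
#' @return Matrix with one row per period (`period * rate` columns).
#' @export
segment_signal <- function(x, trim = 3, period = 1) {
  stopifnot(inherits(x, "nh_signal"))
  n <- length(x$samples)
  ntrim <- round(trim * x$rate)
  nper <- round(period * x$rate)
  keep <- n - 2L * ntrim
  if (keep < nper)
    stop("trial too short: nothing remains after trimming ", trim,
         " s from each end")
  nseg <- keep %/% nper
  seg <- x$samples[(ntrim + 1L):(ntrim + nseg * nper)]
  matrix(seg, nrow = nseg, ncol = nper, byrow = TRUE)
}

#' @rdname segment_signal
#' @param dataset a [trial_set()].
#' @return For `segment_trials`: a list (one element per trial) of lists of
#'   period matrices for `p`, `v`, `y`.
#' @export
segment_trials <- function(dataset, trim = 3, period = 1) {
  stopifnot(inherits(dataset, "trial_set"))
  lapply(dataset$trials, function(tr) list(
    p = segment_signal(tr$p, trim, period),
    v = segment_signal(tr$v, trim, period),
    y = segment_signal(tr$y, trim, period)))
}

#' Periodicity-based signal-to-noise ratio
#'
#' For a channel segmented into stimulus-aligned periods, the periodic
#' (stimulus-locked) part is estimated by the across-period mean; the SNR is
#' \deqn{10 \log_{10} \frac{\mathrm{var}(\bar x)}{\overline{\mathrm{var}}(x_i
#' - \bar x)}}{10 log10( var(mean period) / mean per-period residual var )}.
#' Identical periods (a purely periodic channel) give `Inf`. The estimator
#' is scale-invariant. When several candidate channels are available, the
#' one with maximal SNR is taken as the system output ([select_output()]).
#'
#' @param periods matrix of periods (rows) from [segment_signal()].
#' @return SNR in dB (possibly `Inf` or `-Inf`).
#' @export
estimate_snr <- function(periods) {
  periods <- as.matrix(periods)
  if (nrow(periods) < 2L) stop("need at least 2 periods to estimate SNR")
  m <- colMeans(periods)
  resid <- sweep(periods, 2L, m)
  num <- stats::var(m)
  den <- mean(apply(resid, 1L, stats::var))
  if (den == 0) return(Inf)
  10 * log10(num / den)
}

#' @rdname estimate_snr
#' @param channels named list of period matrices, one per candidate channel.
#' @return For `select_output`: the name (or index) of the channel with the
#'   highest SNR, with the per-channel SNRs as attribute `"snr"`.
#' @export
select_output <- function(channels) {
  snrs <- vapply(channels, estimate_snr, numeric(1))
  best <- which.max(snrs)
  out <- if (!is.null(names(channels))) names(channels)[best] else best
  attr(out, "snr") <- snrs
  out
}

#' Default configuration of a synthetic experiment
#'
#' The study conditions: 10 participants, 7 trials of 36 s at 256 Hz, the
#' 10-component multisine at RMS 0.02 rad with a distinct random phase set
#' per trial, 3 s trimmed from each trial end, 1-s periods, and output noise
#' at 10 dB SNR (white) to emulate a poor-SNR neural recording.
#'
#' @param ... overrides for any field.
#' @return Named list of configuration values.
#' @export
experiment_config <- function(...) {
  cfg <- list(n_participants = 10L, n_trials = 7L, trial_duration = 36,
              rate = 256, period = 1, rms = 0.02,
              frequencies = c(1, 3, 5, 7, 9, 11, 13, 15, 19, 23),
              trim = 3, noise_snr_db = 10, noise_color = "white",
              noise_injection = "process",
              d1 = 4L, d2 = 8L, n1 = 2L, n2 = 2L, ny = 5L,
              rho1 = 0.8, w1 = 1.8, rho2 = 1.6, w2 = 1.8)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Draw ground-truth network parameters from the stability box
#'
#' Input weights and inter-layer weights are drawn uniformly from moderate
#' ranges so the network is clearly nonlinear but not saturated; feedback
#' weights are drawn small and rejected until `sum(|weights_y|) < 0.9`,
#' which (with the output map's slope bound) keeps the free-run recursion a
#' contraction and hence bounded. Inter-layer weights get a random sign and
#' a magnitude bounded away from zero so the output is never degenerate.
#' Node biases are drawn around the firing threshold `w` of their layer's
#' sigmoid, so each node's drive crosses its responsive region: with biases
#' near zero the nodes would idle deep in the sigmoid tail and the
#' "response" would be a nearly-constant trace with tiny variance — not a
#' useful emulation of a stimulus-driven neural signal.
#'
#' @param lags a [lag_spec()].
#' @param seed RNG seed.
#' @param sigmoid_1,sigmoid_2 fixed layer activations.
#' @return An [hnn_params()].
#' @export
draw_hnn_params <- function(lags, seed,
                            sigmoid_1 = sigmoid_spec(0.8, 1.8),
                            sigmoid_2 = sigmoid_spec(1.6, 1.8)) {
  local_seed(seed, {
    nA <- 2 * (lags$n1 + 1); nB <- lags$n2 + 1
    # substantial but contractive feedback: a dominant positive first lag
    # (persistent reverberation) plus smaller signed higher lags.  The
    # output-map slope is bounded by rho2/2 per unit weight, so rejecting
    # sum|wy| >= 1.2 keeps the worst-case loop gain below 1.
    draw_wy <- function() {
      if (lags$ny == 0L) return(numeric(0))
      c(stats::runif(1, 0.6, 1.0),
        if (lags$ny > 1L) stats::runif(lags$ny - 1L, -0.15, 0.15))
    }
    wy <- draw_wy()
    while (sum(abs(wy)) >= 1.2) wy <- draw_wy()
    hnn_params(lags,
               weights_A = stats::runif(nA, -0.6, 0.6),
               weights_B = stats::runif(nB, -0.6, 0.6),
               weights_y = wy,
               weight_AC = sample(c(-1, 1), 1) * stats::runif(1, 0.4, 0.9),
               weight_BC = sample(c(-1, 1), 1) * stats::runif(1, 0.4, 0.9),
               bias_A = sigmoid_1$w + stats::runif(1, -0.6, 0.6),
               bias_B = sigmoid_1$w + stats::runif(1, -0.6, 0.6),
               bias_C = sigmoid_2$w + stats::runif(1, -0.6, 0.6),
               sigmoid_1 = sigmoid_1, sigmoid_2 = sigmoid_2)
  })
}

#' Generate a full synthetic experiment
#'
#' For each synthetic participant: draw ground-truth network parameters
#' (seeded), draw a distinct multisine phase set per trial, fix one
#' participant-wide input normalization (so a single ground-truth model
#' underlies all trials), free-run the network over each trial, and add
#' output noise. The manifest records every seed and the truth parameters,
#' so downstream tests can measure recovery.
#'
#' @param config from [experiment_config()].
#' @param seed master seed; all per-participant and per-trial seeds derive
#'   from it.
#' @return A list: `participants` (list of [trial_set()]s), `truth` (list of
#'   [hnn_params()]), `manifest` (named list of seeds and settings).
#' @export
make_experiment <- function(config = experiment_config(), seed = 1) {
  seed <- as.integer(seed)
  lags <- lag_spec(config$d1, config$d2, config$n1, config$n2, config$ny)
  s1 <- sigmoid_spec(config$rho1, config$w1)
  s2 <- sigmoid_spec(config$rho2, config$w2)
  participants <- vector("list", config$n_participants)
  truth <- vector("list", config$n_participants)
  manifest <- list(seed = seed,
                   n_participants = config$n_participants,
                   n_trials = config$n_trials,
                   trial_duration = config$trial_duration,
                   rate = config$rate, rms = config$rms,
                   noise_snr_db = config$noise_snr_db,
                   noise_color = config$noise_color)
  for (i in seq_len(config$n_participants)) {
    pseed <- (seed * 1009L + i * 9973L) %% 2147483647L
    params <- draw_hnn_params(lags, pseed, s1, s2)
    phases <- make_phase_set(pseed + 1L, config$n_trials,
                             n_freq = length(config$frequencies))
    specs <- lapply(phases, function(ph)
      multisine_spec(config$frequencies, ph, config$rms, config$rate,
                     config$period))
    # one participant-wide input normalization over all trials' p and v
    ps <- lapply(specs, make_multisine, duration = config$trial_duration)
    vs <- lapply(specs, derive_velocity, duration = config$trial_duration)
    input_norm <- list(
      p = fit_normalization(unlist(lapply(ps, `[[`, "samples"))),
      v = fit_normalization(unlist(lapply(vs, `[[`, "samples"))))
    trials <- vector("list", config$n_trials)
    for (tr in seq_len(config$n_trials)) {
      nseed <- (pseed + 31L * tr) %% 2147483647L
      sim <- simulate_ground_truth(
        params, specs[[tr]], duration = config$trial_duration,
        noise = noise_spec(config$noise_snr_db, config$noise_color, nseed,
                           config$noise_injection),
        input_norm = input_norm)
      trials[[tr]] <- list(p = sim$p, v = sim$v, y = sim$y)
    }
    participants[[i]] <- trial_set(sprintf("P%d", i), trials,
                                   rate = config$rate,
                                   period = config$period,
                                   stimulus = specs[[1L]])
    truth[[i]] <- params
    manifest[[sprintf("participant_%d_seed", i)]] <- pseed
    manifest[[sprintf("participant_%d_truth", i)]] <- flatten_params(params)
  }
  list(participants = participants, truth = truth, manifest = manifest)
}
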