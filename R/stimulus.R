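#' Multisine perturbation stimulus specification
#'
#' The wrist-perturbation stimulus is a 1-s-periodic sum of sinusoids at
#' integer frequencies 1, 3, 5, 7, 9, 11, 13, 15, 19, 23 Hz. Component
#' amplitudes are set so that the first three components (1, 3, 5 Hz) carry
#' equal power and components above 5 Hz follow a -20 dB/decade power
#' roll-off anchored at 5 Hz (power proportional to (5/f)^2), with the whole
#' signal scaled to a target root-mean-square of 0.02 rad.
#'
#' @param frequencies positive integer frequencies in Hz (must fit a 1-s
#'   period exactly).
#' @param phases phase of each component in radians; same length as
#'   `frequencies`.
#' @param rms_target target RMS of the position signal, in radians.
#' @param rate sampling rate in samples/second; must exceed twice the highest
#'   frequency.
#' @param period signal period in seconds (the design uses 1 s).
#' @return An object of class `multisine_spec`.
#' @examples
#' sp <- multisine_spec(phases = rep(0, 10))
#' sp$amplitudes[1:3]            # equal-power low-frequency components
#' @export
multisine_spec <- function(frequencies = c(1, 3, 5, 7, 9, 11, 13, 15, 19, 23),
                           phases = rep(0, length(frequencies)),
                           rms_target = 0.02,
                           rate = 256,
                           period = 1) {
  if (length(phases) != length(frequencies))
    stop("phases must have the same length as frequencies")
  if (any(frequencies <= 0))
    stop("frequencies must be positive")
  # integer number of cycles per period, so the signal is exactly periodic
  cyc <- frequencies * period
  if (any(abs(cyc - round(cyc)) > 1e-9))
    stop("each frequency must complete an integer number of cycles per ",
         period, "-s period; offending frequency: ",
         frequencies[which(abs(cyc - round(cyc)) > 1e-9)[1L]], " Hz")
  if (rate <= 2 * max(frequencies))
    stop("rate (", rate, " Hz) must exceed twice the highest frequency (",
         max(frequencies), " Hz)")
  if (rms_target <= 0) stop("rms_target must be positive")

  # relative power: 1 for f <= 5, (5/f)^2 above (power slope -20 dB/decade)
  relpow <- ifelse(frequencies <= 5, 1, (5 / frequencies)^2)
  # amplitude a_i with power a_i^2/2; scale so total RMS hits the target
  a <- sqrt(relpow)
  scale <- rms_target / sqrt(sum(a^2 / 2))
  structure(list(frequencies = as.numeric(frequencies),
                 phases = as.numeric(phases),
                 amplitudes = a * scale,
                 rms_target = rms_target,
                 rate = rate,
                 period = period),
            class = "multisine_spec")
}

#' @export
print.multisine_spec <- function(x, ...) {
  cat(sprintf("<multisine_spec> %d components (%g-%g Hz), RMS %g, %g Hz, %g-s period\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              x$rms_target, x$rate, x$period))
  invisible(x)
}

#' Generate the multisine position stimulus
#'
#' Samples `p(t) = sum_i a_i sin(2 pi f_i t + phi_i)` on a uniform grid.
#' Because every component completes an integer number of cycles per period
#' and the rate is above Nyquist, the sampled sinusoids are exactly
#' orthogonal over one period, so the sampled RMS equals the design RMS to
#' floating-point precision, the signal has zero mean over a period, and it
#' is exactly periodic.
#'
#' @param spec a [multisine_spec()].
#' @param duration length of the generated signal in seconds; defaults to one
#'   period.
#' @return An [nh_signal()] in radians.
#' @examples
#' p <- make_multisine(multisine_spec(phases = rep(0, 10)))
#' sqrt(mean(p$samples^2))   # 0.02
#' @export
make_multisine <- function(spec, duration = spec$period) {
  stopifnot(inherits(spec, "multisine_spec"))
  n <- round(duration * spec$rate)
  t <- (seq_len(n) - 1) / spec$rate
  x <- numeric(n)
  for (i in seq_along(spec$frequencies))
    x <- x + spec$amplitudes[i] *
      sin(2 * pi * spec$frequencies[i] * t + spec$phases[i])
  nh_signal(x, rate = spec$rate, units = "rad")
}

#' Analytic velocity of the multisine stimulus
#'
#' Differentiates the multisine in closed form: each component's amplitude is
#' multiplied by `2 pi f` and its phase advanced by `pi/2` (sine becomes
#' cosine). This avoids the high-frequency noise amplification of numerical
#' differencing; [fd_velocity()] provides the finite-difference alternative
#' for measured signals.
#'
#' @inheritParams make_multisine
#' @return An [nh_signal()] in rad/s.
#' @export
derive_velocity <- function(spec, duration = spec$period) {
  stopifnot(inherits(spec, "multisine_spec"))
  n <- round(duration * spec$rate)
  t <- (seq_len(n) - 1) / spec$rate
  x <- numeric(n)
  for (i in seq_along(spec$frequencies)) {
    w <- 2 * pi * spec$frequencies[i]
    x <- x + spec$amplitudes[i] * w * cos(w * t + spec$phases[i])
  }
  nh_signal(x, rate = spec$rate, units = "rad/s")
}

#' Central-difference velocity of a measured position signal
#'
#' For signals not generated from a [multisine_spec()]. Uses the symmetric
#' difference `(x[k+1] - x[k-1]) * rate / 2` with one-sided differences at
#' the ends.
#'
#' @param p an [nh_signal()] holding position samples.
#' @return An [nh_signal()] in rad/s.
#' @export
fd_velocity <- function(p) {
  stopifnot(inherits(p, "nh_signal"))
  x <- p$samples
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples to differentiate")
  v <- numeric(n)
  v[1L] <- (x[2L] - x[1L]) * p$rate
  v[n] <- (x[n] - x[n - 1L]) * p$rate
  if (n > 2L) v[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * p$rate / 2
  nh_signal(v, rate = p$rate, units = paste0(p$units, "/s"))
}

#' Draw reproducible random phase sets
#'
#' The study drives each trial with a different realization of the same
#' multisine design, distinguished only by the relative phases of the
#' components. Phases do not affect per-component power, so every phase set
#' yields the same power spectrum and RMS.
#'
#' @param seed integer seed; the draw is reproducible and does not disturb
#'   the caller's RNG state.
#' @param count number of phase vectors (the study used 7, one per trial).
#' @param n_freq number of frequency components per vector.
#' @return A list of `count` numeric vectors of phases in `[0, 2*pi)`.
#' @export
make_phase_set <- function(seed, count, n_freq = 10) {
  if (count < 1L) stop("count must be >= 1")
  out <- local_seed(seed, {
    lapply(seq_len(count), function(i) stats::runif(n_freq, 0, 2 * pi))
  })
  out
}

# run expr under a temporary RNG seed, restoring the caller's RNG state
local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Per-component power of a sampled periodic signal
#'
#' Periodogram power at integer frequencies over one period, computed by FFT.
#' Used to verify the equal-power / roll-off design of the stimulus.
#'
#' @param x an [nh_signal()] spanning an integer number of 1-s periods.
#' @param freqs frequencies (Hz) at which to report power.
#' @param period period in seconds.
#' @return Named numeric vector of power (amplitude^2 / 2) per frequency.
#' @export
component_power <- function(x, freqs, period = 1) {
  stopifnot(inherits(x, "nh_signal"))
  n <- round(x$rate * period)
  if (length(x$samples) < n) stop("signal shorter than one period")
  X <- stats::fft(x$samples[seq_len(n)]) / n
  # single-sided amplitude of bin f: 2*|X[f+1]| ; power = amp^2/2
  amp <- 2 * Mod(X[freqs * period + 1L])
  stats::setNames(amp^2 / 2, as.character(freqs))
}
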