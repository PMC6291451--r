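---
title: "Identifying closed-loop neural responses with a hierarchical sigmoid network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying closed-loop neural responses with a hierarchical sigmoid network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a periodic mechanical perturbation is applied to the wrist, the evoked
cortical response is strongly nonlinear and closed-loop: most of the response
power appears at non-stimulated frequencies, and feedback interactions in
thalamocortical circuits make the current response depend on its own recent
history. `narmaxhnn` identifies this kind of system from sampled
position/velocity input and a single response channel, using three model
families inside one nonlinear autoregressive (NARX-type) framework:

* a **hierarchical sigmoid network** whose structure follows the
  somatosensory pathway anatomy,
* a **polynomial NARX** model with terms selected by orthogonal forward
  regression (OFR), and
* a **Volterra-style input-only** polynomial model (no autoregressive
  terms), as the open-loop baseline.

All three are scored by variance accounted for (VAF) under
leave-one-trial-out cross-validation, at one- to three-step-ahead
prediction horizons.

## The model

At sample rate 256 Hz, the output `y(k)` is modeled as a nonlinear function
of three lag groups, reflecting the two muscle-spindle afferent pathways and
cortical feedback:

* fast (group Ia analogue) channel: velocity and position lags
  `v(k-d1), ..., v(k-d1-n1)` and `p(k-d1), ..., p(k-d1-n1)`, with `d1 = 4`
  samples (~16 ms, the shortest somatosensory conduction delay);
* slow (group II analogue) channel: position lags `p(k-d2), ..., p(k-d2-n2)`
  with `d2 = 8` (~32 ms — group II conduction is about half as fast);
* feedback: `y(k-1), ..., y(k-ny)` with `ny = 5` (~20 ms of output memory).

With `n1 = n2 = 2` this gives 14 lagged regressors. The hierarchical
network routes them through two layers: node A (medulla relay) receives the
fast-channel lags, node B the slow-channel lags, and node C (thalamic relay)
combines the two node outputs with the feedback lags. Each node applies the
shifted sigmoid

    S(u) = 1 / (1 + exp(-rho (u - w))) - 1 / (1 + exp(rho w)),

which is zero at zero drive, with fixed constants `(rho, w) = (0.8, 1.8)` in
the first layer and `(1.6, 1.8)` at node C, taken from the neural-mass
modeling literature; they are anatomy-level constants, not trained. The
trainable parameters are 6 input weights into A, 3 into B, 5 feedback
weights, the two inter-layer weights and 3 biases — 19 in total
(`count_parameters(lag_spec())`).

### Node-output scaling

All signals are affinely normalized to `[-1, 1]` on the training fold before
fitting, and every node output is likewise passed through a *fixed* affine
map taking the sigmoid's theoretical range `(-c, 1-c)`,
`c = 1/(1+exp(rho w))`, onto `(-1, 1)`. Two reasons. First, it puts node
outputs and normalized signals on the same scale, so no single weight has to
absorb a large scale disparity. Second, it is required for the model class
to be able to express its own training target at all: the raw sigmoid has a
range of width 1, while a target normalized to `[-1, 1]` has width 2, so a
raw node-C output could never span it. The map has no trainable parameters,
leaving the 19-parameter count intact. A consequence worth knowing: with all
weights and biases zero the network outputs the mapped value
`2 S2(0) + 2 c2 - 1 ≈ -0.894`, not 0.

### Training

The network is trained by Møller's scaled conjugate gradient (SCG) on the
mean squared one-step error, with teacher forcing: the feedback lags in the
regressors are the *measured* outputs, which makes the fit an ordinary
smooth regression rather than a recurrent optimization. SCG uses conjugate
directions with a finite-difference Hessian-vector product and a
Levenberg–Marquardt-style scaling instead of a line search; the analytic
gradient of the two-layer composition is used (and is verified against
central differences in the test suite to 1e-6). Defaults: initial weights
uniform on `[-0.5, 0.5]` (seeded), 5 restarts keeping the best final loss,
up to 2000 iterations, convergence declared when the accepted-step loss
decrease stays below 1e-9 for 20 iterations. Accepted-step loss history is
non-increasing by construction.

The moving-average (noise) lags that the general NARMAX formulation allows
are not used as predictor terms — the k-step-ahead predictors are defined
without them — so the fitted models are NARX-type throughout.

### Baselines and OFR

The polynomial models expand the same 14 regressors (9 input regressors for
the Volterra kind) into all monomials up to degree 2 (configurable) plus a
constant, and select terms greedily by error-reduction ratio:
`ERR_i = <y, q_i>^2 / (<q_i, q_i> <y, y>)` for the candidate orthogonalized
(modified Gram–Schmidt) against the already-selected set. Selection stops at
the term budget (defaults 25 for the NARX polynomial, 46 for Volterra — the
optimal model sizes reported for this paradigm) or when the unexplained
fraction drops to `tol` (default 0.01). ERR ties within 1e-12 go to the
lowest candidate index; candidates whose orthogonalized norm collapses below
`1e-10` of their original norm are recorded and skipped. Coefficients come
from back-substitution on the accumulated unit-upper-triangular system,
which equals least squares on the selected subset.

### Prediction horizons

One-step-ahead prediction uses measured lags only. The h-step predictor
replaces the `h-1` most recent output lags with the model's own previous
predictions (the `(h-1)`-step prediction at `k-1`, the `(h-2)`-step at
`k-2`, ...) and keeps measured values for older lags; input lags are always
measured. Horizon 1 is bitwise identical to one-step prediction, and a
Volterra-kind model (no output lags) predicts identically at every horizon,
so it is reported at a single horizon. Horizons 1–3 are evaluated (12 ms at
256 Hz); if `h-1` exceeds `ny` the substitution saturates at `ny` predicted
lags.

### Scoring

`VAF = 100 (1 - var(yhat - y) / var(y))` with the sample (N-1) variance; it
may be negative, and it is invariant under a shared affine transform of both
series. Cross-validation is leave-one-trial-out: the `[-1, 1]` normalization
and the model are fitted on the training trials only (regressors never
straddle trial boundaries) and the VAF is computed on the normalized scale
over the whole concatenated held-out trial, not per 1-s period — the
simpler convention, and the two differ only through period-boundary edge
effects. Per-participant mean VAFs feed a two-sided paired t-test
(`paired_compare()`); zero-variance differences are flagged degenerate
rather than tested.

## The stimulus

The perturbation is a 1-s-periodic multisine at 1, 3, 5, 7, 9, 11, 13, 15,
19, 23 Hz with equal component power at 1/3/5 Hz and a −20 dB/decade decay
above, anchored at 5 Hz, scaled to RMS 0.02 rad. The decay is interpreted as
a *power* slope (power ∝ (5/f)², amplitude ∝ 1/f), the conventional reading
of dB/decade roll-off figures. Because every component completes an integer
number of cycles per period and the rate is above Nyquist, the sampled
components are exactly orthogonal: the sampled RMS equals the design RMS to
floating-point precision and the signal is exactly periodic. Velocity is
obtained analytically (amplitudes scaled by 2πf, phases advanced by π/2)
rather than by differencing, which would amplify high-frequency error;
`fd_velocity()` exists for measured signals. Per-trial realizations differ
only by their component phases, drawn uniformly on `[0, 2π)` under a seed —
crest-factor-optimized phase designs exist, but plain random phases keep
every trial's power spectrum identical, which is all the analysis relies on.

## The synthetic experiment

Real evoked EEG cannot be bundled, so every stage is exercised on synthetic
experiments generated by the package itself: per participant, ground-truth
network parameters are drawn (seeded), seven multisine phase sets are drawn,
and each trial is generated by *free-running* the network — its own past
outputs serve as the feedback lags, initial outputs zero. Free-run
generation makes teacher-forced refitting a well-posed recovery problem:
on a noiseless experiment, the cross-validated one-step and three-step VAF
of the refitted network exceed 99%.

Ground-truth draws come from a stability box chosen once:

* input weights into A and B uniform on `[-0.6, 0.6]`; inter-layer weights
  with random sign and magnitude in `[0.4, 0.9]` so the output is never
  degenerate;
* node biases around the layer's firing threshold (`w ± 0.6`). With biases
  near zero every node would idle deep in the sigmoid tail (output nearly
  constant at the map floor) — a driven system should cross its responsive
  region;
* feedback weights with a dominant positive first lag in `[0.6, 1.0]` and
  smaller signed higher lags, rejected until `sum(|w_y|) < 1.2`. The output
  map's slope is at most `rho2/2` per unit weight, so this keeps the loop a
  contraction (bounded free run) while leaving genuinely persistent
  autoregressive dynamics — the property the three-step and input-only
  comparisons probe.

Output noise is specified as an SNR in dB relative to the clean free run,
white or 1/f-colored, and is injected *inside* the recursion by default
(process noise): each noisy output feeds back into later outputs, which is
where the noise terms sit in the general NARMAX formulation. This matters
for the model comparison. With purely post-hoc measurement noise, the
predicted (noise-free) lags used by multi-step prediction are *better* than
the measured ones, so three-step prediction can beat one-step, and an
input-only model loses almost nothing — the comparison degenerates. With
process noise the recent output lags carry real information that input-only
models cannot access, reproducing the expected ordering: one-step >
three-step > Volterra-style. Measurement-noise injection remains available
via `noise_spec(injection = "measurement")`.

What the generator does *not* emulate: multichannel scalp mixing, volume
conduction and ICA unmixing, non-stationarity across trials, line noise, or
the cited SNR-selection algorithm of the original recordings —
`estimate_snr()` is a documented periodicity-based surrogate (variance of
the across-period mean over mean residual variance, in dB; `Inf` for a
purely periodic channel; scale-invariant). Passing tests therefore show the
pipeline is correct and well-posed, not that real EEG meets the generator's
assumptions.

## Numerical choices and degenerate inputs

* Sigmoids are evaluated through `plogis`, which saturates without overflow.
* `fit_normalization()` rejects constant signals; VAF rejects zero-variance
  measured series; OFR rejects zero-variance targets.
* A free run that exceeds `|y| > 1e3` aborts naming the parameter set (with
  the bounded output map this indicates a corrupted parameter file rather
  than ordinary instability).
* SCG restarts that hit a non-finite loss are dropped; if all restarts
  diverge the fit fails with diagnostics.
* Seeded draws go through an RNG-state-preserving helper, so library calls
  never disturb the caller's random stream; every experiment records all
  derived seeds and the truth parameters in its manifest.

## Problem sizes used in the shipped checks

The full study-scale conditions (10 participants × 7 trials × 36 s, with
seven-fold cross-validated SCG fits per participant) are what
`experiment_config()` encodes by default, but the shipped test suite and the
acceptance script run the compute-heavy stages at reduced sizes chosen as
this package's own benchmark scale: the noiseless recovery check uses one
participant with 7 × 10-s trials (SCG 600 iterations, 2 restarts), and the
10 dB three-model comparison uses 10 participants with 4 × 10-s trials (SCG
400 iterations, 2 restarts). Structural checks (stimulus spectrum,
segmentation counts, parameter counts) run at full scale. The qualitative
conclusions — recovery above 99% VAF and the one-step > three-step >
input-only ordering — are properties of the method, not of the reduced
sizes; longer trials only tighten them.

## Known limitations

* The delay structure (`d1`, `d2`) is fixed from anatomy, not estimated.
* The polynomial degree for the baselines defaults to 2 and the candidate
  lag ranges equal the network's; neither is tuned per dataset.
* The noise model is additive and stationary; no moving-average noise terms
  are fitted (an extended-least-squares refinement was considered and left
  out: the predictors never use noise lags, so it would affect coefficient
  estimation only).
* VAF over whole held-out trials slightly differs from per-period averaging
  when trials are short.
* Multi-step prediction beyond three steps works mechanically (substitution
  saturates at `ny` predicted lags) but is outside the validated surface.
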