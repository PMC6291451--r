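# narmaxhnn

Nonlinear system identification of closed-loop neural responses to periodic
joint perturbations, for researchers modeling how cortical activity tracks
a mechanical stimulus. The package fits and compares three model families
for a sampled dual-input/single-output system — position `p(k)` and
velocity `v(k)` of a wrist perturbation in, one response channel `y(k)`
out — inside one nonlinear autoregressive framework:

* **Hierarchical sigmoid network (HNN).** The 14 lagged regressors of

  ```
  y(k) = f( y(k-1), ..., y(k-5),
            v(k-4), ..., v(k-6),  p(k-4), ..., p(k-6),   # fast (Ia) channel
            p(k-8), ..., p(k-10) )                       # slow (II) channel
  ```

  are routed through an anatomically structured two-layer network: node A
  (medulla relay) takes the fast-channel velocity/position lags, node B the
  slow-channel position lags, node C (thalamic relay) combines both with
  the feedback lags. Each node applies the shifted sigmoid
  `S(u) = 1/(1+e^{-ρ(u-w)}) - 1/(1+e^{ρw})` with fixed constants
  `(ρ, w) = (0.8, 1.8)` in layer 1 and `(1.6, 1.8)` in layer 2; the
  19 trainable weights/biases are fitted by scaled conjugate gradient on
  the mean squared one-step error.
* **Polynomial NARX** — degree-2 monomials of the same regressors, terms
  selected by orthogonal forward regression ranked by error-reduction
  ratio (ERR).
* **Volterra-style input-only polynomial** — same selection, no
  autoregressive terms: the open-loop baseline.

Models are scored by variance accounted for,
`VAF = 100·(1 − var(ŷ − y)/var(y))`, under leave-one-trial-out
cross-validation at one- to three-step-ahead horizons (multi-step
prediction recursively substitutes the model's own recent predictions for
the most recent output lags). A multisine stimulus generator (1–23 Hz,
RMS 0.02 rad, −20 dB/decade power roll-off above 5 Hz) and a
trial-structured synthetic-experiment generator make the whole pipeline
runnable without any recorded data. See `vignettes/narmaxhnn-methods.Rmd`
for the modeling details and design choices.

## Worked example

Simulate one synthetic participant (4 trials of 10 s at 256 Hz, 10 dB
in-loop output noise), then cross-validate the hierarchical network and the
input-only baseline:

```r
library(narmaxhnn)

lag_spec()
#> <lag_spec> d1=4 d2=8 n1=2 n2=2 ny=5 (14 regressors, burn-in 10)
count_parameters(lag_spec())
#> [1] 19

cfg <- experiment_config(n_participants = 1, n_trials = 4,
                         trial_duration = 10, noise_snr_db = 10)
exp <- make_experiment(cfg, seed = 1)
ts <- exp$participants[[1]]
ts
#> <trial_set> participant P1: 4 trials of 10 s @ 256 Hz

fit <- cross_validate(ts,
  model_spec("hnn", lag_spec(),
             train = train_config(max_iterations = 400, restarts = 2,
                                  seed = 1)),
  horizons = 1:3)
fit
#> <fit_report> participant P1, 4 folds
#>  model horizon mean_vaf    sd_vaf n_folds
#>    hnn       1 91.24848 0.2325848       4
#>    hnn       2 88.26636 0.4435646       4
#>    hnn       3 87.32603 0.6027607       4

volt <- cross_validate(ts, model_spec("volterra", lag_spec()), horizons = 1)
volt
#> <fit_report> participant P1, 4 folds
#>     model horizon mean_vaf    sd_vaf n_folds
#>  volterra       1 87.06682 0.5674261       4
```

Reading the numbers: the held-out one-step VAF of 91.2% sits just below the
~91% ceiling implied by 10 dB noise; VAF decays with horizon (88.3% at two
steps, 87.3% at three) because prediction errors recirculate through the
feedback lags; and the input-only Volterra model (87.1%) loses exactly the
variance carried by those feedback lags, which it cannot see.

`run_simulate()` / `run_fit_evaluate()` wrap the same steps for whole
multi-participant experiments (with per-participant summary tables and
paired t-tests), and `inst/cli/narmaxhnn.R` exposes them as `simulate`,
`fit-evaluate`, `predict` and `report` shell commands.

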