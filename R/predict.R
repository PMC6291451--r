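#' One-step-ahead prediction
#'
#' Predicts `y(k)` for every `k` past the lag burn-in using measured lags
#' only (teacher forcing): the model never sees its own previous
#' predictions.
#'
#' @param model a fitted model (`hnn_model` from [train_scg()] results via
#'   [as_hnn_model()], or a `poly_model`).
#' @param p,v,y position, velocity and measured output (same scale the model
#'   was fitted on).
#' @param lags a [lag_spec()]; defaults to the model's own.
#' @return An object of class `prediction_run`: `horizon`, `predicted`,
#'   `measured` (aligned numeric vectors), `first_index`.
#' @export
predict_osa <- function(model, p, v, y, lags = model$lags) {
  predict_msa(model, p, v, y, horizon = 1L, lags = lags)
}

#' Multi-step-ahead prediction
#'
#' For horizon `h`, the prediction at time `k` replaces the `h-1` most
#' recent output lags with the model's own previous predictions (the
#' `h-1`-step prediction at `k-1`, the `h-2`-step at `k-2`, ...) and uses
#' measured output for older lags; input lags are always measured. Horizon 1
#' is exactly one-step-ahead prediction. If `h-1` exceeds `ny`, the
#' substitution saturates: all `ny` output lags are predicted values.
#'
#' The `h`-step series starts `h-1` samples after the one-step series, where
#' the full chain of predicted lags first exists.
#'
#' @inheritParams predict_osa
#' @param horizon number of steps ahead, >= 1.
#' @return A `prediction_run` (see [predict_osa()]).
#' @export
predict_msa <- function(model, p, v, y, horizon = 1L, lags = model$lags) {
  if (!inherits(model, "nh_model")) stop("model must be a fitted nh_model")
  if (horizon < 1L) stop("horizon must be >= 1")
  horizon <- as.integer(horizon)
  ys <- as_samples(y)
  R <- build_regressors(p, v, y, lags)
  fi <- burn_in(lags)
  N <- length(ys)
  ycols <- regressor_blocks(lags)$y
  levels <- vector("list", horizon)
  lev1 <- rep(NA_real_, N)
  lev1[(fi + 1L):N] <- predict_rows(model, R)
  levels[[1L]] <- lev1
  if (horizon > 1L) for (h in 2:horizon) {
    ks <- (fi + h):N
    if (length(ks) < 1L)
      stop("signals too short for horizon ", h, " with this lag spec")
    Rh <- R[ks - fi, , drop = FALSE]
    for (j in seq_len(min(h - 1L, lags$ny)))
      Rh[, ycols[j]] <- levels[[h - j]][ks - j]
    levh <- rep(NA_real_, N)
    levh[ks] <- predict_rows(model, Rh)
    levels[[h]] <- levh
  }
  ks <- (fi + horizon):N
  structure(list(horizon = horizon,
                 predicted = levels[[horizon]][ks],
                 measured = ys[ks],
                 first_index = fi + horizon - 1L),
            class = "prediction_run")
}

#' @export
print.prediction_run <- function(x, ...) {
  cat(sprintf("<prediction_run> horizon %d, %d samples, VAF = %.2f%%\n",
              x$horizon, length(x$predicted),
              vaf(x$predicted, x$measured)))
  invisible(x)
}

#' Variance accounted for
#'
#' \deqn{VAF = 100\,[1 - \mathrm{var}(\hat y - y)/\mathrm{var}(y)]}
#' with the sample (N-1) variance. 100% is a perfect prediction; predicting
#' the mean gives 0%; worse-than-mean predictions go negative.
#'
#' @param predicted,measured aligned numeric vectors (or [nh_signal()]s /
#'   a single `prediction_run` as `predicted`).
#' @return VAF in percent.
#' @examples
#' vaf(c(1, 2, 3, 5), c(1, 2, 3, 4))   # 85
#' @export
vaf <- function(predicted, measured = NULL) {
  if (inherits(predicted, "prediction_run")) {
    measured <- predicted$measured
    predicted <- predicted$predicted
  }
  yh <- as_samples(predicted); y <- as_samples(measured)
  if (length(yh) != length(y)) stop("predicted and measured length mismatch")
  if (length(y) < 2L) stop("need at least 2 samples")
  vy <- stats::var(y)
  if (vy == 0) stop("measured signal has zero variance; VAF undefined")
  100 * (1 - stats::var(yh - y) / vy)
}

#' Paired comparison of per-subject model performances
#'
#' Two-sided paired t-test on per-subject mean VAFs (or any paired scores).
#' When the paired differences have zero variance the t statistic is
#' undefined; the result is flagged `degenerate` (with `t = 0, p = 1` for
#' the all-equal case) and a warning is raised.
#'
#' @param vafs_a,vafs_b equal-length paired score vectors, `n >= 2`.
#' @return A list: `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_compare <- function(vafs_a, vafs_b) {
  a <- as.numeric(vafs_a); b <- as.numeric(vafs_b)
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    warning("paired differences have zero variance; t-test degenerate")
    return(list(t = if (all(d == 0)) 0 else NA_real_,
                p = if (all(d == 0)) 1 else NA_real_,
                df = length(d) - 1L, mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(d), degenerate = FALSE)
}

#' Wrap trained network parameters as a predictive model
#'
#' @param params an [hnn_params()] (e.g. `train_scg(...)$params`).
#' @return An `hnn_model` usable with [predict_osa()] / [predict_msa()].
#' @export
as_hnn_model <- function(params) {
  stopifnot(inherits(params, "hnn_params"))
  hnn_model(params)
}
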