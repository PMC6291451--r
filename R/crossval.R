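#' Trial-structured dataset for one participant
#'
#' Holds the repeated perturbation trials of one (synthetic) participant:
#' each trial is a `(p, v, y)` triple of aligned [nh_signal()]s sharing one
#' sampling rate and stimulus design.
#'
#' @param participant identifier.
#' @param trials list of `list(p =, v =, y =)` signal triples.
#' @param rate sampling rate in samples/second.
#' @param period stimulus period in seconds.
#' @param stimulus optional [multisine_spec()] reference.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(participant, trials, rate = 256, period = 1,
                      stimulus = NULL) {
  if (!length(trials)) stop("need at least one trial")
  for (tr in trials) {
    if (!all(c("p", "v", "y") %in% names(tr)))
      stop("each trial must be a list with elements p, v, y")
    n <- length(as_samples(tr$p))
    if (length(as_samples(tr$v)) != n || length(as_samples(tr$y)) != n)
      stop("p, v, y must be aligned within each trial")
  }
  structure(list(participant = participant, trials = trials,
                 rate = rate, period = period, stimulus = stimulus),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  n <- length(as_samples(x$trials[[1]]$p))
  cat(sprintf("<trial_set> participant %s: %d trials of %g s @ %g Hz\n",
              as.character(x$participant), length(x$trials),
              n / x$rate, x$rate))
  invisible(x)
}

#' Model specification for fitting and comparison
#'
#' @param kind `"hnn"` (hierarchical network), `"narmax"` (polynomial
#'   NARMAX), or `"volterra"` (input-only polynomial).
#' @param lags a [lag_spec()].
#' @param train a [train_config()] (hnn only).
#' @param max_degree,budget,tol polynomial/OFR settings (see
#'   [fit_poly_model()]); `budget = NULL` uses the kind-specific default.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = c("hnn", "narmax", "volterra"),
                       lags = lag_spec(), train = train_config(),
                       max_degree = 2, budget = NULL, tol = 0.01) {
  kind <- match.arg(kind)
  structure(list(kind = kind, lags = lags, train = train,
                 max_degree = max_degree, budget = budget, tol = tol),
            class = "model_spec")
}

# build regressors + aligned target per trial on normalized signals, then
# stack: lags never straddle a trial boundary
stack_regressors <- function(trials_norm, lags) {
  Rs <- lapply(trials_norm, function(tr)
    build_regressors(tr$p, tr$v, tr$y, lags))
  fi <- burn_in(lags)
  ts <- lapply(trials_norm, function(tr) {
    y <- as_samples(tr$y)
    y[(fi + 1L):length(y)]
  })
  list(R = do.call(rbind, Rs), target = unlist(ts, use.names = FALSE))
}

# fit one model on (already normalized) training trials
fit_model_on_trials <- function(trials_norm, spec, seed_offset = 0L) {
  st <- stack_regressors(trials_norm, spec$lags)
  if (spec$kind == "hnn") {
    cfg <- spec$train
    cfg$seed <- as.integer(cfg$seed + seed_offset)
    fit <- train_scg(st$R, st$target, spec$lags, config = cfg)
    m <- hnn_model(fit$params)
    m$train_loss <- fit$loss
    m
  } else {
    fit_poly_model_regressors(st$R, st$target, spec$lags, spec$kind,
                              max_degree = spec$max_degree,
                              budget = spec$budget, tol = spec$tol)
  }
}

#' Leave-one-trial-out cross-validation
#'
#' One fold per trial: the model (and the `[-1, 1]` range normalization of
#' `p`, `v`, `y`) is fitted on the remaining trials and scored by [vaf()] on
#' the held-out trial at each requested horizon, on the normalized scale
#' over the whole held-out trial. Volterra-kind models contain no
#' autoregressive terms, so multi-step prediction is not defined for them;
#' they are reported at horizon 1 only.
#'
#' @param dataset a [trial_set()].
#' @param spec a [model_spec()].
#' @param horizons prediction horizons to score (default 1:3).
#' @return An object of class `fit_report`: `table`
#'   (data.frame fold/model/horizon/vaf), `summary` (mean and sd per
#'   horizon), `residuals` (per-fold one-step residual series), `models`
#'   (per-fold fitted models), `participant`.
#' @export
cross_validate <- function(dataset, spec, horizons = 1:3) {
  stopifnot(inherits(dataset, "trial_set"), inherits(spec, "model_spec"))
  n_tr <- length(dataset$trials)
  if (n_tr < 2L) stop("cross-validation needs at least 2 trials")
  if (spec$kind == "volterra") horizons <- 1L
  rows <- list(); residuals <- list(); models <- list()
  for (fold in seq_len(n_tr)) {
    train_trials <- dataset$trials[-fold]
    test_trial <- dataset$trials[[fold]]
    norm <- list(
      p = fit_normalization(unlist(lapply(train_trials, function(tr) as_samples(tr$p)))),
      v = fit_normalization(unlist(lapply(train_trials, function(tr) as_samples(tr$v)))),
      y = fit_normalization(unlist(lapply(train_trials, function(tr) as_samples(tr$y)))))
    norm_trial <- function(tr) list(
      p = apply_normalization(as_samples(tr$p), norm$p),
      v = apply_normalization(as_samples(tr$v), norm$v),
      y = apply_normalization(as_samples(tr$y), norm$y))
    model <- fit_model_on_trials(lapply(train_trials, norm_trial), spec,
                                 seed_offset = 101L * fold)
    te <- norm_trial(test_trial)
    for (h in horizons) {
      run <- predict_msa(model, te$p, te$v, te$y, horizon = h)
      rows[[length(rows) + 1L]] <- data.frame(
        fold = fold, model = spec$kind, horizon = h,
        vaf = vaf(run))
      if (h == 1L) residuals[[fold]] <- run$predicted - run$measured
    }
    models[[fold]] <- model
  }
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(tab, tab$horizon), function(d)
    data.frame(model = spec$kind, horizon = d$horizon[1L],
               mean_vaf = mean(d$vaf), sd_vaf = stats::sd(d$vaf),
               n_folds = nrow(d))))
  rownames(summ) <- NULL
  structure(list(table = tab, summary = summ, residuals = residuals,
                 models = models, participant = dataset$participant),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> participant %s, %d folds\n",
              as.character(x$participant), max(x$table$fold)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Export a per-fold fit report as delimited text
#'
#' Columns: fold, model, horizon, vaf.
#'
#' @param report a `fit_report` from [cross_validate()].
#' @param path file path.
#' @export
write_fit_report <- function(report, path) {
  utils::write.table(report$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Summary table across participants
#'
#' Wide per-participant table of mean VAFs per model and horizon (one-step
#' and the largest requested horizon for autoregressive models, the single
#' horizon for Volterra) with mean and standard-deviation footer rows —
#' the usual layout for reporting cross-validated model comparisons.
#'
#' @param reports list of lists of `fit_report`s, one inner list per
#'   participant (any mix of model kinds).
#' @return A data.frame; participant rows then `Mean` and `Std.` rows.
#' @export
vaf_summary_table <- function(reports) {
  rows <- list()
  for (rep_list in reports) {
    if (inherits(rep_list, "fit_report")) rep_list <- list(rep_list)
    row <- list(participant = as.character(rep_list[[1L]]$participant))
    for (rp in rep_list) {
      s <- rp$summary
      for (i in seq_len(nrow(s))) {
        nm <- sprintf("%s_h%d", s$model[i], s$horizon[i])
        row[[nm]] <- s$mean_vaf[i]
      }
    }
    rows[[length(rows) + 1L]] <- as.data.frame(row, check.names = FALSE)
  }
  tab <- do.call(rbind, rows)
  num <- vapply(tab, is.numeric, TRUE)
  footer_mean <- tab[1, , drop = FALSE]
  footer_mean$participant <- "Mean"
  footer_sd <- tab[1, , drop = FALSE]
  footer_sd$participant <- "Std."
  for (cn in names(tab)[num]) {
    footer_mean[[cn]] <- mean(tab[[cn]])
    footer_sd[[cn]] <- stats::sd(tab[[cn]])
  }
  rbind(tab, footer_mean, footer_sd)
}
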