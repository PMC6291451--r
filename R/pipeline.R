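#' Run configuration with study defaults
#'
#' Flat key-value configuration driving the end-to-end pipeline; defaults
#' reproduce the study settings (lag structure d1=4, d2=8, n1=n2=2, ny=5;
#' sigmoid constants (0.8, 1.8) and (1.6, 1.8); 256 Hz; horizons 1-3;
#' 10-participant, 7-trial experiment at RMS 0.02 rad). Read and written as
#' plain `key = value` text via [read_run_config()] / [write_run_config()].
#'
#' @param ... overrides for any field.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- c(experiment_config(),
           list(horizons = 1:3,
                models = c("hnn", "narmax", "volterra"),
                seed = 1L,
                max_iterations = 2000L, restarts = 5L,
                train_tol = 1e-9, patience = 20L,
                max_degree = 2L, ofr_tol = 0.01,
                out_dir = "narmaxhnn_out"))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path file path of a key-value config file.
#' @export
read_run_config <- function(path) {
  kv <- read_keyvalue(path)
  do.call(run_config, kv)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  write_keyvalue(unclass(config), path)
}

# deterministic content hash of a key-value structure (config/manifest),
# via its canonical text form
keyvalue_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_keyvalue(x, tmp)
  unname(tools::md5sum(tmp))
}

#' Write / read one trial as delimited text
#'
#' Four tab-separated columns with one header line: `time_s`, `p`, `v`,
#' `y`; full double precision, so a round trip is exact to text precision.
#'
#' @param trial list with [nh_signal()]s `p`, `v`, `y`.
#' @param path file path.
#' @param rate sampling rate (read side).
#' @export
write_trial <- function(trial, path) {
  n <- length(trial$p$samples)
  df <- data.frame(
    time_s = format((seq_len(n) - 1) / trial$p$rate, digits = 17, trim = TRUE),
    p = format(trial$p$samples, digits = 17, trim = TRUE),
    v = format(trial$v$samples, digits = 17, trim = TRUE),
    y = format(trial$y$samples, digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path, rate = 256) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "numeric")
  if (!all(c("p", "v", "y") %in% names(df)))
    stop("malformed trial file '", path, "': missing p/v/y columns")
  if (nrow(df) >= 2L) rate <- 1 / (df$time_s[2L] - df$time_s[1L])
  list(p = nh_signal(df$p, rate, "rad"),
       v = nh_signal(df$v, rate, "rad/s"),
       y = nh_signal(df$y, rate, "a.u."))
}

#' Simulate an experiment and write it to disk
#'
#' Runs [make_experiment()] under the configuration and writes one trial
#' file per participant and trial plus a `manifest.txt` recording every
#' seed, the truth parameters, and the config hash.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, the in-memory experiment (see [make_experiment()])
#'   with `out_dir` and `manifest_hash` attached.
#' @export
run_simulate <- function(config = run_config(), quiet = FALSE) {
  exp <- make_experiment(config, seed = config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(exp$participants)) {
    ts <- exp$participants[[i]]
    for (tr in seq_along(ts$trials))
      write_trial(ts$trials[[tr]],
                  file.path(config$out_dir,
                            sprintf("participant%02d_trial%02d.tsv", i, tr)))
  }
  exp$manifest$config_hash <- keyvalue_hash(unclass(config))
  write_keyvalue(exp$manifest, file.path(config$out_dir, "manifest.txt"))
  exp$out_dir <- config$out_dir
  exp$manifest_hash <- keyvalue_hash(exp$manifest)
  if (!quiet)
    message(length(exp$participants), " participants written to ",
            config$out_dir, " (manifest hash ", exp$manifest_hash, ")")
  invisible(exp)
}

#' Load a simulated experiment from disk
#'
#' @param dir directory written by [run_simulate()].
#' @return List with `participants` (list of [trial_set()]s) and `manifest`.
#' @export
load_experiment <- function(dir) {
  mf <- file.path(dir, "manifest.txt")
  if (!file.exists(mf)) stop("no manifest.txt in ", dir)
  manifest <- read_keyvalue(mf)
  files <- list.files(dir, pattern = "^participant\\d+_trial\\d+\\.tsv$",
                      full.names = TRUE)
  if (!length(files)) stop("no trial files found in ", dir)
  ids <- sub("^participant(\\d+)_trial\\d+\\.tsv$", "\\1", basename(files))
  participants <- lapply(sort(unique(ids)), function(id) {
    fs <- sort(files[ids == id])
    trials <- lapply(fs, read_trial, rate = manifest$rate)
    trial_set(sprintf("P%d", as.integer(id)), trials,
              rate = manifest$rate, period = 1)
  })
  list(participants = participants, manifest = manifest)
}

#' Cross-validated fit and comparison over a whole experiment
#'
#' For every participant and every requested model kind, runs
#' leave-one-trial-out [cross_validate()] at the requested horizons, then
#' assembles the per-participant summary table and the paired t-tests
#' between model kinds (on per-participant mean VAFs: hierarchical network
#' vs polynomial NARMAX at each horizon, and each against the Volterra
#' model at one step).
#'
#' @param experiment output of [make_experiment()] / [run_simulate()] /
#'   [load_experiment()].
#' @param config a [run_config()].
#' @param quiet suppress per-participant progress messages.
#' @return A list: `reports` (per participant, per model `fit_report`s),
#'   `table` ([vaf_summary_table()] output), `tests` (named list of
#'   [paired_compare()] results), `config_hash`.
#' @export
run_fit_evaluate <- function(experiment, config = run_config(),
                             quiet = FALSE) {
  lags <- lag_spec(config$d1, config$d2, config$n1, config$n2, config$ny)
  tc <- train_config(max_iterations = config$max_iterations,
                     restarts = config$restarts, seed = config$seed,
                     tol = config$train_tol, patience = config$patience)
  specs <- lapply(config$models, function(kind)
    model_spec(kind, lags = lags, train = tc,
               max_degree = config$max_degree, tol = config$ofr_tol))
  names(specs) <- config$models
  reports <- list()
  for (i in seq_along(experiment$participants)) {
    ts <- experiment$participants[[i]]
    reps <- lapply(specs, function(sp)
      cross_validate(ts, sp, horizons = config$horizons))
    reports[[i]] <- reps
    if (!quiet)
      message("participant ", ts$participant, ": ",
              paste(vapply(reps, function(r)
                sprintf("%s OSA %.1f%%", r$summary$model[1],
                        r$summary$mean_vaf[r$summary$horizon == 1]), ""),
                collapse = ", "))
  }
  tab <- vaf_summary_table(reports)
  # per-participant mean VAF per model/horizon for the paired tests
  pull <- function(model, horizon) {
    vapply(reports, function(reps) {
      s <- reps[[model]]$summary
      s$mean_vaf[s$horizon == horizon]
    }, numeric(1))
  }
  tests <- list()
  hmax <- max(config$horizons)
  if (length(experiment$participants) < 2L) {
    # paired tests need at least two participants
    return(list(reports = reports, table = tab, tests = tests,
                config_hash = keyvalue_hash(unclass(config))))
  }
  if (all(c("hnn", "narmax") %in% config$models)) {
    tests$hnn_vs_narmax_osa <- paired_compare(pull("hnn", 1), pull("narmax", 1))
    if (hmax > 1)
      tests[[sprintf("hnn_vs_narmax_h%d", hmax)]] <-
        paired_compare(pull("hnn", hmax), pull("narmax", hmax))
  }
  if (all(c("hnn", "volterra") %in% config$models))
    tests$hnn_vs_volterra_osa <- paired_compare(pull("hnn", 1),
                                                pull("volterra", 1))
  if (all(c("narmax", "volterra") %in% config$models))
    tests$narmax_vs_volterra_osa <- paired_compare(pull("narmax", 1),
                                                   pull("volterra", 1))
  list(reports = reports, table = tab, tests = tests,
       config_hash = keyvalue_hash(unclass(config)))
}

#' Write the evaluation outputs as delimited text
#'
#' Writes `summary_table.tsv` (per-participant mean VAFs with Mean/Std.
#' footer), `folds.tsv` (every fold/model/horizon VAF) and
#' `paired_tests.tsv` into `dir`.
#'
#' @param results output of [run_fit_evaluate()].
#' @param dir output directory.
#' @export
write_evaluation <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(results$table, file.path(dir, "summary_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  folds <- do.call(rbind, lapply(seq_along(results$reports), function(i)
    do.call(rbind, lapply(results$reports[[i]], function(r)
      cbind(participant = as.character(r$participant), r$table)))))
  utils::write.table(folds, file.path(dir, "folds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tdf <- do.call(rbind, lapply(names(results$tests), function(nm) {
    tt <- results$tests[[nm]]
    data.frame(comparison = nm, t = tt$t, df = tt$df, p = tt$p,
               mean_diff = tt$mean_diff, degenerate = tt$degenerate)
  }))
  if (!is.null(tdf))
    utils::write.table(tdf, file.path(dir, "paired_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
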