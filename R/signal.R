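#' Uniformly sampled signal
#'
#' Lightweight container for a uniformly sampled real-valued time series:
#' a numeric sample vector, a sampling rate in samples/second, and a unit
#' label (`"rad"`, `"rad/s"`, `"a.u."`, ...).
#'
#' @param samples numeric vector of finite values, length >= 1.
#' @param rate sampling rate in samples per second, > 0.
#' @param units unit label for the sample values.
#' @return An object of class `nh_signal`.
#' @examples
#' s <- nh_signal(sin(2 * pi * (0:255) / 256), rate = 256, units = "rad")
#' length(s$samples)
#' @export
nh_signal <- function(samples, rate, units = "a.u.") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("signal must contain at least one sample")
  if (!all(is.finite(samples))) stop("signal samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("rate must be a single positive number")
  structure(list(samples = samples, rate = rate, units = as.character(units)),
            class = "nh_signal")
}

#' @export
print.nh_signal <- function(x, ...) {
  cat(sprintf("<nh_signal> %d samples @ %g Hz [%s], range [%.4g, %.4g]\n",
              length(x$samples), x$rate, x$units,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.nh_signal <- function(x) length(x$samples)

# coerce: accept either nh_signal or bare numeric (rate supplied by caller)
as_samples <- function(x) {
  if (inherits(x, "nh_signal")) x$samples else as.numeric(x)
}

#' Write / read a signal as two-column delimited text
#'
#' Plain-text interchange format: one header line, then `time_s<TAB>value`
#' rows. Values are written with full double precision (17 significant
#' digits) so a write/read round trip reproduces the samples to better than
#' 1e-12 relative error.
#'
#' @param x an [nh_signal()].
#' @param path file path.
#' @return `write_signal` returns `path` invisibly; `read_signal` returns an
#'   [nh_signal()].
#' @export
write_signal <- function(x, path) {
  stopifnot(inherits(x, "nh_signal"))
  t <- (seq_along(x$samples) - 1) / x$rate
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("time_s\tvalue\t# rate=%s units=%s",
                     format(x$rate, digits = 17), x$units), con)
  writeLines(paste(format(t, digits = 17, scientific = TRUE, trim = TRUE),
                   format(x$samples, digits = 17, scientific = TRUE, trim = TRUE),
                   sep = "\t"), con)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("malformed signal file '", path, "': fewer than 2 lines")
  hdr <- lines[[1L]]
  rate <- as.numeric(sub(".*rate=([^ ]+).*", "\\1", hdr))
  units <- sub(".*units=(.*)$", "\\1", hdr)
  if (!is.finite(rate))
    stop("malformed signal file '", path, "': cannot parse rate from header")
  body <- lines[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("malformed signal file '", path, "': line ", bad[[1L]] + 1L,
         " does not have two tab-separated fields")
  vals <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (anyNA(vals))
    stop("malformed signal file '", path, "': non-numeric value at line ",
         which(is.na(vals))[[1L]] + 1L)
  nh_signal(vals, rate = rate, units = units)
}

# Flat key-value text serialization used for parameter sets, manifests and
# run configs.  Numeric scalars/vectors are written with 17 significant
# digits (round-trip exact for doubles); vectors are comma-separated.
write_keyvalue <- function(x, path) {
  fmt1 <- function(v) {
    if (is.numeric(v)) paste(format(v, digits = 17, trim = TRUE), collapse = ",")
    else paste(as.character(v), collapse = ",")
  }
  lines <- vapply(names(x), function(nm) paste0(nm, " = ", fmt1(x[[nm]])), "")
  writeLines(lines, path)
  invisible(path)
}

read_keyvalue <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed key-value file '", path, "': line ", i,
                     " has no '='")
    key <- trimws(substr(ln, 1L, eq - 1L))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}
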