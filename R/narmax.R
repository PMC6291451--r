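#' Delay and memory structure of the dual-input NARMAX model
#'
#' The model has two afferent input channels with distinct conduction delays:
#' a fast channel (group Ia analogue) carrying velocity and position with
#' delay `d1`, and a slow channel (group II analogue) carrying position only
#' with delay `d2`; `n1` and `n2` are the memory depths of the two channels
#' and `ny` the autoregressive feedback depth. Defaults are the study
#' settings at 256 Hz: `d1 = 4` (~16 ms), `d2 = 8` (~32 ms),
#' `n1 = n2 = 2` (~8 ms), `ny = 5` (~20 ms).
#'
#' @param d1 fast-pathway delay in samples.
#' @param d2 slow-pathway delay in samples; `d1 <= d2`.
#' @param n1 fast-pathway memory in samples.
#' @param n2 slow-pathway memory in samples.
#' @param ny feedback memory in samples.
#' @return An object of class `lag_spec`.
#' @examples
#' lag_spec()          # the study defaults
#' @export
lag_spec <- function(d1 = 4, d2 = 8, n1 = 2, n2 = 2, ny = 5) {
  v <- c(d1 = d1, d2 = d2, n1 = n1, n2 = n2, ny = ny)
  if (any(v < 0) || any(v != round(v)))
    stop("all lag parameters must be non-negative integers")
  if (d1 > d2)
    stop("d1 must not exceed d2: the fast (Ia) pathway has the shorter delay")
  v <- stats::setNames(as.integer(v), names(v))
  structure(as.list(v), class = "lag_spec")
}

#' @export
print.lag_spec <- function(x, ...) {
  cat(sprintf("<lag_spec> d1=%d d2=%d n1=%d n2=%d ny=%d (%d regressors, burn-in %d)\n",
              x$d1, x$d2, x$n1, x$n2, x$ny, n_regressors(x), burn_in(x)))
  invisible(x)
}

#' Number of lagged regressor columns implied by a lag structure
#'
#' `2*(n1+1)` velocity and position lags on the fast channel, `(n2+1)`
#' position lags on the slow channel, and `ny` feedback lags.
#'
#' @param lags a [lag_spec()].
#' @return Integer column count (14 for the study defaults).
#' @export
n_regressors <- function(lags) {
  as.integer(2L * (lags$n1 + 1L) + (lags$n2 + 1L) + lags$ny)
}

#' Burn-in: earliest time index with complete lags
#'
#' A row at time `k` (1-based) is predictable only when all its lags exist,
#' i.e. `k > max(d1 + n1, d2 + n2, ny)`. The returned value is that maximum
#' — the number of leading samples consumed by the lag structure (10 for the
#' study defaults).
#'
#' @param lags a [lag_spec()].
#' @return Integer number of unusable leading samples.
#' @export
burn_in <- function(lags) {
  as.integer(max(lags$d1 + lags$n1, lags$d2 + lags$n2, lags$ny))
}

#' Build the lagged regressor matrix
#'
#' One row per predictable time index `k = burn_in(lags)+1, ..., N`; columns
#' are, in order: `v(k-d1) ... v(k-d1-n1)`, `p(k-d1) ... p(k-d1-n1)`,
#' `p(k-d2) ... p(k-d2-n2)`, `y(k-1) ... y(k-ny)`. Column names record the
#' (variable, lag) identity, e.g. `"p[k-8]"`.
#'
#' @param p,v,y position, velocity and output signals ([nh_signal()] or bare
#'   numeric vectors) of equal length.
#' @param lags a [lag_spec()].
#' @return Numeric matrix with attributes `first_index` (the burn-in) and
#'   `lags`; `nrow = length - burn_in`.
#' @export
build_regressors <- function(p, v, y, lags) {
  stopifnot(inherits(lags, "lag_spec"))
  p <- as_samples(p); v <- as_samples(v); y <- as_samples(y)
  n <- length(p)
  if (length(v) != n || length(y) != n)
    stop("p, v and y must have the same length")
  fi <- burn_in(lags)
  if (n < fi + 1L)
    stop("signals too short: need more than ", fi, " samples for this lag spec")
  k <- (fi + 1L):n                      # predictable time indices
  lag_col <- function(x, lag) x[k - lag]
  cols <- list(); labs <- character(0)
  for (j in 0:lags$n1) {
    cols <- c(cols, list(lag_col(v, lags$d1 + j)))
    labs <- c(labs, sprintf("v[k-%d]", lags$d1 + j))
  }
  for (j in 0:lags$n1) {
    cols <- c(cols, list(lag_col(p, lags$d1 + j)))
    labs <- c(labs, sprintf("p[k-%d]", lags$d1 + j))
  }
  for (j in 0:lags$n2) {
    cols <- c(cols, list(lag_col(p, lags$d2 + j)))
    labs <- c(labs, sprintf("p[k-%d]", lags$d2 + j))
  }
  for (j in seq_len(lags$ny)) {
    cols <- c(cols, list(lag_col(y, j)))
    labs <- c(labs, sprintf("y[k-%d]", j))
  }
  R <- do.call(cbind, cols)
  colnames(R) <- labs
  attr(R, "first_index") <- fi
  attr(R, "lags") <- lags
  R
}

# index ranges of the column blocks within a regressor matrix
regressor_blocks <- function(lags) {
  nA <- 2L * (lags$n1 + 1L); nB <- lags$n2 + 1L
  list(A = seq_len(nA),                         # v and p lags, fast channel
       B = nA + seq_len(nB),                    # p lags, slow channel
       y = nA + nB + seq_len(lags$ny))          # feedback lags
}

#' Enumerate polynomial model terms
#'
#' All distinct monomials of the regressor columns up to `max_degree`,
#' including the constant term. A term is stored as a sorted integer vector
#' of column indices (empty vector = constant); its degree is its length.
#' Volterra-kind enumeration excludes any term containing a feedback (`y`)
#' lag, making the model purely input-driven.
#'
#' @param lags a [lag_spec()].
#' @param max_degree maximum monomial degree, >= 1.
#' @param kind `"narmax"` (all regressors) or `"volterra"` (input lags only).
#' @return List of integer vectors with a `labels` attribute; length equals
#'   `choose(m + max_degree, max_degree)` for `m` admissible columns.
#' @export
enumerate_terms <- function(lags, max_degree = 2, kind = c("narmax", "volterra")) {
  kind <- match.arg(kind)
  if (max_degree < 1) stop("max_degree must be >= 1")
  blocks <- regressor_blocks(lags)
  cols <- if (kind == "volterra") c(blocks$A, blocks$B)
          else c(blocks$A, blocks$B, blocks$y)
  terms <- list(integer(0))               # constant
  prev <- list(integer(0))
  for (d in seq_len(max_degree)) {
    nxt <- list()
    for (t in prev) {
      lo <- if (length(t)) t[length(t)] else cols[1L]
      for (cix in cols[cols >= lo]) nxt[[length(nxt) + 1L]] <- c(t, cix)
    }
    terms <- c(terms, nxt)
    prev <- nxt
  }
  attr(terms, "kind") <- kind
  terms
}

# human-readable labels for terms given regressor column names
term_labels <- function(terms, colnames) {
  vapply(terms, function(t) {
    if (!length(t)) return("1")
    paste(colnames[t], collapse = "*")
  }, "")
}

# evaluate terms on a regressor matrix -> candidate design matrix
term_matrix <- function(terms, R) {
  M <- matrix(1, nrow = nrow(R), ncol = length(terms))
  for (j in seq_along(terms)) {
    t <- terms[[j]]
    for (cix in t) M[, j] <- M[, j] * R[, cix]
  }
  colnames(M) <- term_labels(terms, colnames(R))
  M
}

#' Orthogonal forward regression with error-reduction ratios
#'
#' Greedy term selection for polynomial models. At each step the remaining
#' candidate columns are orthogonalized against the selected set (modified
#' Gram-Schmidt) and the candidate maximizing the error-reduction ratio
#' \deqn{ERR_i = \frac{\langle y, q_i\rangle^2}{\langle q_i, q_i\rangle
#' \langle y, y\rangle}}{ERR_i = (y.q_i)^2 / ((q_i.q_i)(y.y))}
#' is added. Selection stops when the unexplained fraction `1 - sum(ERR)`
#' drops to `tol` or `budget` terms are selected. Coefficients are recovered
#' by back-substitution on the unit-upper-triangular system accumulated
#' during orthogonalization. Ties in ERR within 1e-12 go to the lowest
#' candidate index; candidates whose orthogonalized norm collapses are
#' skipped (recorded in `skipped`).
#'
#' @param candidates numeric matrix, one column per candidate term.
#' @param target numeric response vector (or [nh_signal()]).
#' @param budget maximum number of selected terms, >= 1.
#' @param tol stop once `1 - sum(ERR) <= tol`.
#' @return An object of class `ofr_selection`: `selected` (candidate column
#'   indices in selection order), `coefficients`, `err`, `labels`, `skipped`.
#' @export
ofr_select <- function(candidates, target, budget = 25L, tol = 0.01) {
  y <- as_samples(target)
  X <- as.matrix(candidates)
  if (nrow(X) != length(y)) stop("candidates and target length mismatch")
  if (budget < 1L) stop("budget must be >= 1")
  if (stats::var(y) == 0) stop("target has zero variance; nothing to select")
  yy <- sum(y * y)
  M <- ncol(X)
  norms0 <- sqrt(colSums(X^2))
  W <- X                                  # progressively orthogonalized
  A <- matrix(0, nrow = 0, ncol = M)      # accumulated MGS coefficients
  active <- norms0 > 0
  selected <- integer(0); err <- numeric(0); g <- numeric(0)
  skipped <- integer(0)
  while (length(selected) < budget && any(active)) {
    qq <- colSums(W^2)
    degenerate <- active & qq <= (1e-10 * norms0)^2
    if (any(degenerate)) {
      skipped <- c(skipped, which(degenerate))
      active[degenerate] <- FALSE
      if (!any(active)) break
    }
    yq <- as.numeric(crossprod(W, y))
    e <- ifelse(active, yq^2 / (qq * yy), -Inf)
    best <- max(e)
    pick <- which(e >= best - 1e-12)[1L]  # lowest index on ties
    q <- W[, pick]
    qn <- sum(q * q)
    selected <- c(selected, pick)
    err <- c(err, unname(e[pick]))
    g <- c(g, yq[pick] / qn)
    active[pick] <- FALSE
    if (1 - sum(err) <= tol) break
    if (any(active)) {
      alpha <- as.numeric(crossprod(W[, active, drop = FALSE], q)) / qn
      W[, active] <- W[, active, drop = FALSE] -
        outer(q, alpha)
      row <- numeric(M); row[active] <- alpha
      A <- rbind(A, row)
    } else {
      A <- rbind(A, numeric(M))
    }
  }
  if (!length(selected)) stop("no candidate could be selected")
  # unit-upper-triangular back-substitution: theta_i = g_i - sum r_ij theta_j
  m <- length(selected)
  theta <- numeric(m)
  for (i in m:1) {
    s <- g[i]
    if (i < m) for (j in (i + 1L):m) s <- s - A[i, selected[j]] * theta[j]
    theta[i] <- s
  }
  structure(list(selected = selected,
                 coefficients = theta,
                 err = err,
                 labels = colnames(X)[selected],
                 skipped = skipped),
            class = "ofr_selection")
}

#' @export
print.ofr_selection <- function(x, ...) {
  cat(sprintf("<ofr_selection> %d terms, sum(ERR) = %.6f\n",
              length(x$selected), sum(x$err)))
  df <- data.frame(order = seq_along(x$selected), term = x$labels,
                   coefficient = x$coefficients, ERR = x$err)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Fit a polynomial NARMAX or Volterra model by OFR
#'
#' Enumerates monomial terms over the lagged regressors (autoregressive lags
#' included for `"narmax"`, excluded for `"volterra"`), then selects terms by
#' [ofr_select()]. The defaults mirror the study's reported optimal model
#' sizes: a 25-term polynomial NARMAX and a 46-term Volterra model.
#'
#' @inheritParams build_regressors
#' @param kind `"narmax"` or `"volterra"`.
#' @param max_degree maximum monomial degree (default 2).
#' @param budget maximum number of selected terms; `NULL` picks 25 for
#'   narmax, 46 for volterra.
#' @param tol ERR stopping tolerance passed to [ofr_select()].
#' @return An object of class `poly_model` usable with [predict_osa()] and
#'   [predict_msa()].
#' @export
fit_poly_model <- function(p, v, y, lags, kind = c("narmax", "volterra"),
                           max_degree = 2, budget = NULL, tol = 0.01) {
  kind <- match.arg(kind)
  if (is.null(budget)) budget <- if (kind == "narmax") 25L else 46L
  R <- build_regressors(p, v, y, lags)
  ys <- as_samples(y)
  fit_poly_model_regressors(R, ys[(burn_in(lags) + 1L):length(ys)],
                            lags, kind, max_degree, budget, tol)
}

# core fit given an assembled regressor matrix and aligned target
fit_poly_model_regressors <- function(R, target, lags, kind, max_degree = 2,
                                      budget = NULL, tol = 0.01) {
  if (is.null(budget)) budget <- if (kind == "narmax") 25L else 46L
  terms <- enumerate_terms(lags, max_degree = max_degree, kind = kind)
  Cm <- term_matrix(terms, R)
  sel <- ofr_select(Cm, target, budget = budget, tol = tol)
  structure(list(kind = kind,
                 lags = lags,
                 terms = terms[sel$selected],
                 coefficients = sel$coefficients,
                 err = sel$err,
                 labels = sel$labels),
            class = c("poly_model", "nh_model"))
}

#' @export
print.poly_model <- function(x, ...) {
  cat(sprintf("<poly_model kind=%s> %d terms, sum(ERR) = %.6f\n",
              x$kind, length(x$terms), sum(x$err)))
  print(data.frame(term = x$labels, coefficient = x$coefficients,
                   ERR = x$err), row.names = FALSE)
  invisible(x)
}

#' Serialize a polynomial model as a delimited-text table
#'
#' Columns: selection order, term label, coefficient, ERR. [read_poly_table()]
#' reads it back as a data frame (the term structure itself is re-derivable
#' from the labels and lag spec).
#'
#' @param model a `poly_model`.
#' @param path file path.
#' @export
write_poly_table <- function(model, path) {
  df <- data.frame(order = seq_along(model$terms),
                   term = model$labels,
                   coefficient = format(model$coefficients, digits = 17),
                   ERR = format(model$err, digits = 17))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_poly_table
#' @export
read_poly_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("integer", "character", "numeric", "numeric"))
}

# one-step model output for each row of a regressor matrix
predict_rows <- function(model, R) UseMethod("predict_rows")

#' @export
predict_rows.poly_model <- function(model, R) {
  out <- numeric(nrow(R))
  for (j in seq_along(model$terms)) {
    t <- model$terms[[j]]
    col <- rep(1, nrow(R))
    for (cix in t) col <- col * R[, cix]
    out <- out + model$coefficients[j] * col
  }
  out
}
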