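#' Shifted-sigmoid synaptic activation
#'
#' The synapse model
#' \deqn{S(u) = \frac{1}{1+e^{-\rho(u-w)}} - \frac{1}{1+e^{\rho w}}}
#' with slope `rho` and firing threshold `w`. The subtracted constant makes
#' `S(0) = 0` (no output at zero drive); the function is strictly increasing
#' and bounded in `(-c, 1-c)` with `c = 1/(1+exp(rho*w))`. Defaults follow
#' the neural-mass literature: `(rho, w) = (0.8, 1.8)` at the first
#' (medulla) layer and `(1.6, 1.8)` at the second (thalamus) layer; they are
#' fixed constants, not trained.
#'
#' @param rho slope parameter, > 0.
#' @param w firing threshold.
#' @return An object of class `sigmoid_spec`.
#' @export
sigmoid_spec <- function(rho = 0.8, w = 1.8) {
  if (rho <= 0) stop("rho must be positive")
  structure(list(rho = rho, w = w), class = "sigmoid_spec")
}

#' @rdname sigmoid_spec
#' @param u input drive (any numeric vector).
#' @param spec a [sigmoid_spec()].
#' @export
hnn_sigmoid <- function(u, spec) {
  # plogis is the numerically safe logistic (saturates without overflow)
  stats::plogis(spec$rho * (u - spec$w)) - stats::plogis(-spec$rho * spec$w)
}

# derivative dS/du = rho * s * (1 - s), s = logistic(rho (u - w))
hnn_sigmoid_deriv <- function(u, spec) {
  s <- stats::plogis(spec$rho * (u - spec$w))
  spec$rho * s * (1 - s)
}

# lower bound c of the sigmoid range (-c, 1-c)
sigmoid_floor <- function(spec) stats::plogis(-spec$rho * spec$w)

# fixed affine map taking the sigmoid's theoretical range (-c, 1-c) onto
# (-1, 1): x -> 2*(x + c) - 1.  Applied to every node output so all signals
# in the network live on the same [-1, 1] scale; it has no trainable
# parameters, so the model parameter count is unchanged.
node_output_map <- function(x, spec) 2 * (x + sigmoid_floor(spec)) - 1

#' Trainable parameters of the hierarchical network
#'
#' Two first-layer nodes: node A receives the fast-channel (Ia) velocity and
#' position lags, node B the slow-channel (II) position lags. The
#' second-layer node C combines the (range-normalized) outputs of A and B
#' with the autoregressive feedback lags. Trainable parameters: `2*(n1+1)`
#' weights into A, `(n2+1)` weights into B, `ny` feedback weights into C,
#' the two A->C / B->C weights, and three biases — 19 in total for the study
#' lag settings. The sigmoid constants are fixed.
#'
#' @param lags a [lag_spec()].
#' @param weights_A,weights_B,weights_y,weight_AC,weight_BC,bias_A,bias_B,bias_C
#'   numeric parameter values; defaults are zeros.
#' @param sigmoid_1,sigmoid_2 first/second-layer [sigmoid_spec()]s.
#' @return An object of class `hnn_params`.
#' @export
hnn_params <- function(lags,
                       weights_A = numeric(2 * (lags$n1 + 1)),
                       weights_B = numeric(lags$n2 + 1),
                       weights_y = numeric(lags$ny),
                       weight_AC = 0, weight_BC = 0,
                       bias_A = 0, bias_B = 0, bias_C = 0,
                       sigmoid_1 = sigmoid_spec(0.8, 1.8),
                       sigmoid_2 = sigmoid_spec(1.6, 1.8)) {
  stopifnot(inherits(lags, "lag_spec"))
  if (length(weights_A) != 2 * (lags$n1 + 1))
    stop("weights_A must have length 2*(n1+1) = ", 2 * (lags$n1 + 1))
  if (length(weights_B) != lags$n2 + 1)
    stop("weights_B must have length n2+1 = ", lags$n2 + 1)
  if (length(weights_y) != lags$ny)
    stop("weights_y must have length ny = ", lags$ny)
  structure(list(lags = lags,
                 weights_A = as.numeric(weights_A),
                 weights_B = as.numeric(weights_B),
                 weights_y = as.numeric(weights_y),
                 weight_AC = as.numeric(weight_AC),
                 weight_BC = as.numeric(weight_BC),
                 bias_A = as.numeric(bias_A),
                 bias_B = as.numeric(bias_B),
                 bias_C = as.numeric(bias_C),
                 sigmoid_1 = sigmoid_1,
                 sigmoid_2 = sigmoid_2),
            class = "hnn_params")
}

#' @export
print.hnn_params <- function(x, ...) {
  cat(sprintf("<hnn_params> %d trainable parameters (d1=%d d2=%d n1=%d n2=%d ny=%d)\n",
              count_parameters(x$lags), x$lags$d1, x$lags$d2,
              x$lags$n1, x$lags$n2, x$lags$ny))
  invisible(x)
}

#' Trainable parameter count of the hierarchical network
#'
#' `2*(n1+1) + (n2+1) + ny + 2 + 3`: input weights into nodes A and B,
#' feedback weights, the two inter-layer weights, and three biases. The
#' study settings give 19.
#'
#' @param lags a [lag_spec()].
#' @return Integer.
#' @examples
#' count_parameters(lag_spec())   # 19
#' @export
count_parameters <- function(lags) {
  stopifnot(inherits(lags, "lag_spec"))
  as.integer(2 * (lags$n1 + 1) + (lags$n2 + 1) + lags$ny + 2 + 3)
}

# flatten / unflatten the trainable vector (order fixed; length must equal
# count_parameters)
flatten_params <- function(params) {
  c(params$weights_A, params$weights_B, params$weights_y,
    params$weight_AC, params$weight_BC,
    params$bias_A, params$bias_B, params$bias_C)
}

unflatten_params <- function(theta, lags,
                             sigmoid_1 = sigmoid_spec(0.8, 1.8),
                             sigmoid_2 = sigmoid_spec(1.6, 1.8)) {
  nA <- 2 * (lags$n1 + 1); nB <- lags$n2 + 1; ny <- lags$ny
  if (length(theta) != count_parameters(lags))
    stop("parameter vector has length ", length(theta), ", expected ",
         count_parameters(lags))
  i <- 0
  take <- function(k) { out <- theta[(i + 1):(i + k)]; i <<- i + k; out }
  hnn_params(lags,
             weights_A = take(nA), weights_B = take(nB), weights_y = take(ny),
             weight_AC = take(1), weight_BC = take(1),
             bias_A = take(1), bias_B = take(1), bias_C = take(1),
             sigmoid_1 = sigmoid_1, sigmoid_2 = sigmoid_2)
}

#' Forward pass of the hierarchical network
#'
#' For each regressor row (layout of [build_regressors()]):
#' node A output `S1(bias_A + weights_A . [v-lags, p-lags fast])`, node B
#' output `S1(bias_B + weights_B . [p-lags slow])`; both are mapped from the
#' sigmoid's theoretical range onto `(-1, 1)` by a fixed affine map, as are
#' all node outputs, and combined at node C:
#' `S2(bias_C + weight_AC*A + weight_BC*B + weights_y . [y-lags])`, again
#' range-mapped to `(-1, 1)`. The network output therefore lives on the same
#' `[-1, 1]` scale as the normalized signals it is trained against.
#'
#' @param R regressor matrix from [build_regressors()] (or a single row).
#' @param params an [hnn_params()].
#' @return Numeric vector of network outputs, one per row.
#' @export
hnn_forward <- function(R, params) {
  if (is.null(dim(R))) R <- matrix(R, nrow = 1)
  if (ncol(R) != n_regressors(params$lags))
    stop("regressor matrix has ", ncol(R), " columns, expected ",
         n_regressors(params$lags))
  blocks <- regressor_blocks(params$lags)
  preA <- params$bias_A +
    as.numeric(R[, blocks$A, drop = FALSE] %*% params$weights_A)
  preB <- params$bias_B +
    as.numeric(R[, blocks$B, drop = FALSE] %*% params$weights_B)
  outA <- node_output_map(hnn_sigmoid(preA, params$sigmoid_1), params$sigmoid_1)
  outB <- node_output_map(hnn_sigmoid(preB, params$sigmoid_1), params$sigmoid_1)
  preC <- params$bias_C + params$weight_AC * outA + params$weight_BC * outB +
    as.numeric(R[, blocks$y, drop = FALSE] %*% params$weights_y)
  node_output_map(hnn_sigmoid(preC, params$sigmoid_2), params$sigmoid_2)
}

# mean squared one-step error and its analytic gradient wrt the flattened
# parameter vector.  Used by the SCG trainer; verified against finite
# differences in the test suite.
hnn_loss_grad <- function(theta, R, target, lags,
                          sigmoid_1 = sigmoid_spec(0.8, 1.8),
                          sigmoid_2 = sigmoid_spec(1.6, 1.8),
                          want_grad = TRUE) {
  blocks <- regressor_blocks(lags)
  nA <- length(blocks$A); nB <- length(blocks$B); ny <- length(blocks$y)
  wA <- theta[seq_len(nA)]
  wB <- theta[nA + seq_len(nB)]
  wy <- theta[nA + nB + seq_len(ny)]
  wAC <- theta[nA + nB + ny + 1]; wBC <- theta[nA + nB + ny + 2]
  bA <- theta[nA + nB + ny + 3]; bB <- theta[nA + nB + ny + 4]
  bC <- theta[nA + nB + ny + 5]
  XA <- R[, blocks$A, drop = FALSE]
  XB <- R[, blocks$B, drop = FALSE]
  XY <- R[, blocks$y, drop = FALSE]
  preA <- bA + as.numeric(XA %*% wA)
  preB <- bB + as.numeric(XB %*% wB)
  outA <- node_output_map(hnn_sigmoid(preA, sigmoid_1), sigmoid_1)
  outB <- node_output_map(hnn_sigmoid(preB, sigmoid_1), sigmoid_1)
  preC <- bC + wAC * outA + wBC * outB + as.numeric(XY %*% wy)
  yhat <- node_output_map(hnn_sigmoid(preC, sigmoid_2), sigmoid_2)
  res <- yhat - target
  n <- length(target)
  loss <- mean(res^2)
  if (!want_grad) return(list(loss = loss))
  # d yhat / d preC : the range map scales the sigmoid derivative by 2
  dC <- 2 * hnn_sigmoid_deriv(preC, sigmoid_2)
  base <- (2 / n) * res * dC              # dL/d preC per sample
  dA <- 2 * hnn_sigmoid_deriv(preA, sigmoid_1)
  dB <- 2 * hnn_sigmoid_deriv(preB, sigmoid_1)
  gA <- as.numeric(crossprod(XA, base * wAC * dA))
  gB <- as.numeric(crossprod(XB, base * wBC * dB))
  gy <- as.numeric(crossprod(XY, base))
  grad <- c(gA, gB, gy,
            sum(base * outA), sum(base * outB),
            sum(base * wAC * dA), sum(base * wBC * dB), sum(base))
  list(loss = loss, grad = grad)
}

#' Range normalization fitted on the training fold
#'
#' Affine map sending the training-fold minimum to -1 and maximum to +1,
#' applied unchanged to test data (test values may fall outside `[-1, 1]`).
#'
#' @param x training samples ([nh_signal()] or numeric).
#' @return An object of class `norm_spec` with fields `offset`, `scale`
#'   (mapping is `(x - offset) * scale`).
#' @export
fit_normalization <- function(x) {
  x <- as_samples(x)
  lo <- min(x); hi <- max(x)
  if (hi == lo) stop("cannot normalize a constant signal (zero range)")
  structure(list(offset = (hi + lo) / 2, scale = 2 / (hi - lo)),
            class = "norm_spec")
}

#' @rdname fit_normalization
#' @param spec a `norm_spec`.
#' @export
apply_normalization <- function(x, spec) {
  s <- as_samples(x)
  out <- (s - spec$offset) * spec$scale
  if (inherits(x, "nh_signal")) nh_signal(out, rate = x$rate, units = "norm")
  else out
}

#' @rdname fit_normalization
#' @export
invert_normalization <- function(x, spec) {
  s <- as_samples(x)
  out <- s / spec$scale + spec$offset
  if (inherits(x, "nh_signal")) nh_signal(out, rate = x$rate, units = "a.u.")
  else out
}

#' Training schedule for the scaled-conjugate-gradient fit
#'
#' @param max_iterations iteration cap per restart.
#' @param restarts number of seeded random initializations; the best final
#'   loss wins.
#' @param seed RNG seed for the initializations.
#' @param tol convergence: stop when the accepted-step loss decrease stays
#'   below `tol` for `patience` consecutive iterations.
#' @param patience see `tol`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(max_iterations = 2000, restarts = 5, seed = 1,
                         tol = 1e-9, patience = 20) {
  stopifnot(max_iterations >= 1, restarts >= 1, tol > 0, patience >= 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 restarts = as.integer(restarts),
                 seed = as.integer(seed), tol = tol,
                 patience = as.integer(patience)),
            class = "train_config")
}

#' Train the hierarchical network by scaled conjugate gradient
#'
#' Minimizes the mean squared one-step (teacher-forced) prediction error
#' with Møller's scaled conjugate gradient: conjugate search directions with
#' a Hessian-vector product approximated by a forward gradient difference
#' and a Levenberg-Marquardt-style scaling `lambda`, no line search. Each
#' restart starts from weights drawn uniformly on `[-0.5, 0.5]` (seeded);
#' the restart with the lowest final training loss is returned. The recorded
#' loss history contains accepted steps only and is non-increasing.
#'
#' @param R regressor matrix from [build_regressors()] (signals already
#'   normalized).
#' @param target normalized output aligned with the rows of `R`.
#' @param lags a [lag_spec()].
#' @param config a [train_config()].
#' @param sigmoid_1,sigmoid_2 fixed layer activations.
#' @param init optional [hnn_params()] used as the initialization of the
#'   first restart (e.g. warm starts).
#' @return A list: `params` ([hnn_params()]), `loss` (final MSE),
#'   `history` (accepted-step losses), `restart` (index of winning restart).
#' @export
train_scg <- function(R, target, lags, config = train_config(),
                      sigmoid_1 = sigmoid_spec(0.8, 1.8),
                      sigmoid_2 = sigmoid_spec(1.6, 1.8),
                      init = NULL) {
  target <- as_samples(target)
  if (nrow(R) != length(target)) stop("regressors and target length mismatch")
  np <- count_parameters(lags)
  if (nrow(R) < 10 * np)
    warning("fewer than 10 rows per trainable parameter (", nrow(R), " rows, ",
            np, " parameters); the fit may be poorly determined")
  inits <- local_seed(config$seed, {
    lapply(seq_len(config$restarts), function(i)
      stats::runif(np, -0.5, 0.5))
  })
  if (!is.null(init)) inits[[1L]] <- flatten_params(init)
  best <- NULL
  for (r in seq_len(config$restarts)) {
    run <- scg_minimize(inits[[r]],
                        function(th, want_grad = TRUE)
                          hnn_loss_grad(th, R, target, lags,
                                        sigmoid_1, sigmoid_2, want_grad),
                        max_iter = config$max_iterations,
                        tol = config$tol, patience = config$patience)
    if (is.null(run)) next                    # diverged (non-finite loss)
    if (is.null(best) || run$loss < best$loss) {
      best <- run; best$restart <- r
    }
  }
  if (is.null(best))
    stop("all ", config$restarts, " SCG restarts diverged (non-finite loss); ",
         "check input scaling")
  list(params = unflatten_params(best$theta, lags, sigmoid_1, sigmoid_2),
       loss = best$loss, history = best$history, restart = best$restart)
}

# Møller's scaled conjugate gradient on a smooth objective.
# fn(theta, want_grad) -> list(loss, grad).  Returns NULL if the loss is
# non-finite at initialization.
scg_minimize <- function(theta, fn, max_iter = 2000, tol = 1e-9,
                         patience = 20, sigma0 = 1e-5) {
  ev <- fn(theta)
  if (!is.finite(ev$loss)) return(NULL)
  f <- ev$loss; g <- ev$grad
  history <- f
  r <- -g                                   # steepest-descent residual
  p <- r                                    # search direction
  lambda <- 1e-6; lambda_bar <- 0
  success <- TRUE
  small <- 0
  n <- length(theta)
  delta_raw <- 0                            # p' H p estimate, kept on reject
  for (k in seq_len(max_iter)) {
    p2 <- sum(p * p)
    if (p2 < 1e-30) break
    if (success) {                          # second-order information
      sigma <- sigma0 / sqrt(p2)
      g2 <- fn(theta + sigma * p)$grad
      delta_raw <- sum(p * (g2 + r)) / sigma   # r = -g, so g2 - g = g2 + r
    }
    delta_k <- delta_raw + (lambda - lambda_bar) * p2
    if (delta_k <= 0) {                     # make the Hessian surrogate PD
      lambda_bar <- 2 * (lambda - delta_k / p2)
      delta_k <- -delta_k + lambda * p2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta_k
    theta_new <- theta + alpha * p
    ev_new <- fn(theta_new)
    f_new <- ev_new$loss
    Delta <- if (is.finite(f_new)) 2 * delta_k * (f - f_new) / mu^2 else -1
    if (Delta >= 0) {                       # accepted step
      dec <- f - f_new
      theta <- theta_new; f <- f_new
      r_new <- -ev_new$grad
      lambda_bar <- 0
      success <- TRUE
      history <- c(history, f)
      beta <- (sum(r_new * r_new) - sum(r_new * r)) / mu
      p <- if (k %% n == 0) r_new else r_new + beta * p
      r <- r_new
      if (Delta >= 0.75) lambda <- lambda / 4
      small <- if (dec < tol) small + 1 else 0
      if (small >= patience) break
      if (sum(r * r) < 1e-24) break
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (Delta < 0.25) lambda <- lambda + delta_k * (1 - Delta) / p2
    if (!is.finite(lambda) || lambda > 1e12) lambda <- 1e12
  }
  list(theta = theta, loss = f, history = history)
}

#' Serialize / deserialize network parameters as key-value text
#'
#' Writes every weight vector, bias, sigmoid constant and the lag structure
#' with 17 significant digits; a write/read round trip reproduces the
#' parameters exactly.
#'
#' @param params an [hnn_params()].
#' @param path file path.
#' @export
write_hnn_params <- function(params, path) {
  kv <- list(d1 = params$lags$d1, d2 = params$lags$d2,
             n1 = params$lags$n1, n2 = params$lags$n2, ny = params$lags$ny,
             weights_A = params$weights_A, weights_B = params$weights_B,
             weights_y = params$weights_y,
             weight_AC = params$weight_AC, weight_BC = params$weight_BC,
             bias_A = params$bias_A, bias_B = params$bias_B,
             bias_C = params$bias_C,
             sigmoid_1 = c(params$sigmoid_1$rho, params$sigmoid_1$w),
             sigmoid_2 = c(params$sigmoid_2$rho, params$sigmoid_2$w))
  write_keyvalue(kv, path)
}

#' @rdname write_hnn_params
#' @export
read_hnn_params <- function(path) {
  kv <- read_keyvalue(path)
  lags <- lag_spec(kv$d1, kv$d2, kv$n1, kv$n2, kv$ny)
  hnn_params(lags,
             weights_A = kv$weights_A, weights_B = kv$weights_B,
             weights_y = kv$weights_y,
             weight_AC = kv$weight_AC, weight_BC = kv$weight_BC,
             bias_A = kv$bias_A, bias_B = kv$bias_B, bias_C = kv$bias_C,
             sigmoid_1 = sigmoid_spec(kv$sigmoid_1[1], kv$sigmoid_1[2]),
             sigmoid_2 = sigmoid_spec(kv$sigmoid_2[1], kv$sigmoid_2[2]))
}

# hnn model wrapper so prediction code can dispatch uniformly
hnn_model <- function(params) {
  structure(list(kind = "hnn", lags = params$lags, params = params),
            class = c("hnn_model", "nh_model"))
}

#' @export
predict_rows.hnn_model <- function(model, R) hnn_forward(R, model$params)
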