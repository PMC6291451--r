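test_that("shifted sigmoid passes through zero, saturates, and is monotone", {
  s1 <- sigmoid_spec(0.8, 1.8)
  s2 <- sigmoid_spec(1.6, 1.8)
  expect_identical(hnn_sigmoid(0, s1), 0)
  expect_identical(hnn_sigmoid(0, s2), 0)
  # closed-form values at the threshold and in the saturation limit
  expect_equal(hnn_sigmoid(1.8, s1), 0.5 - 1 / (1 + exp(1.44)),
               tolerance = 1e-12)
  expect_equal(hnn_sigmoid(1e6, s2), 1 - 1 / (1 + exp(2.88)),
               tolerance = 1e-12)
  u <- seq(-30, 30, length.out = 400)
  expect_true(all(diff(hnn_sigmoid(u, s1)) > 0))
  c1 <- 1 / (1 + exp(s1$rho * s1$w))
  expect_true(all(hnn_sigmoid(c(-1e9, 1e9), s1) > -c1 - 1e-15))
  expect_true(all(hnn_sigmoid(c(-1e9, 1e9), s1) < 1 - c1 + 1e-15))
  expect_error(sigmoid_spec(rho = -1), "positive")
})

test_that("parameter count matches the flattened trainable vector for any lag spec", {
  expect_identical(count_parameters(lag_spec()), 19L)
  expect_identical(count_parameters(lag_spec(n1 = 0, n2 = 0, ny = 1)), 9L)
  expect_identical(count_parameters(lag_spec(n1 = 1, n2 = 1, ny = 2)), 13L)
  set.seed(8)
  for (i in 1:10) {
    lg <- lag_spec(d1 = sample(0:3, 1), d2 = sample(3:6, 1),
                   n1 = sample(0:3, 1), n2 = sample(0:3, 1),
                   ny = sample(1:6, 1))
    par <- draw_hnn_params(lg, seed = i)
    expect_identical(count_parameters(lg),
                     length(narmaxhnn:::flatten_params(par)))
    # flatten/unflatten round trip
    back <- narmaxhnn:::unflatten_params(narmaxhnn:::flatten_params(par), lg)
    expect_equal(narmaxhnn:::flatten_params(back),
                 narmaxhnn:::flatten_params(par))
  }
})

test_that("network forward pass matches an independent scalar evaluation", {
  lags <- study_lags()
  # all parameters zero: output is the range-mapped second-layer sigmoid at 0
  p0 <- hnn_params(lags)
  R <- matrix(rnorm(5 * 14), 5)
  c2 <- 1 / (1 + exp(1.6 * 1.8))
  expect_equal(hnn_forward(R, p0), rep(2 * (0 + c2) - 1, 5))

  # zero feedback weights sever the dependence on y lags
  pz <- draw_hnn_params(lags, seed = 2)
  pz$weights_y <- numeric(5)
  R2 <- R; R2[, 10:14] <- rnorm(25)
  expect_equal(hnn_forward(R, pz), hnn_forward(R2, pz))

  # unit weights, zero biases, all inputs 0.1: nested closed form by hand
  pu <- hnn_params(lags,
                   weights_A = rep(1, 6), weights_B = rep(1, 3),
                   weights_y = rep(1, 5), weight_AC = 1, weight_BC = 1)
  row <- rep(0.1, 14)
  S <- function(u, rho, w) 1 / (1 + exp(-rho * (u - w))) - 1 / (1 + exp(rho * w))
  mapn <- function(x, rho, w) 2 * (x + 1 / (1 + exp(rho * w))) - 1
  outA <- mapn(S(0.6, 0.8, 1.8), 0.8, 1.8)
  outB <- mapn(S(0.3, 0.8, 1.8), 0.8, 1.8)
  outC <- mapn(S(outA + outB + 0.5, 1.6, 1.8), 1.6, 1.8)
  expect_equal(hnn_forward(row, pu), outC, tolerance = 1e-14)

  expect_error(hnn_forward(matrix(0, 2, 9), pu), "columns")
})

test_that("analytic network gradient agrees with central finite differences", {
  set.seed(12)
  lags <- study_lags()
  R <- matrix(rnorm(60 * 14), 60)
  tgt <- rnorm(60)
  th <- runif(19, -0.5, 0.5)
  an <- narmaxhnn:::hnn_loss_grad(th, R, tgt, lags)
  h <- 1e-6
  fd <- vapply(seq_along(th), function(i) {
    tp <- th; tm <- th
    tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
    (narmaxhnn:::hnn_loss_grad(tp, R, tgt, lags, want_grad = FALSE)$loss -
     narmaxhnn:::hnn_loss_grad(tm, R, tgt, lags, want_grad = FALSE)$loss) / (2 * h)
  }, numeric(1))
  expect_equal(an$grad, fd, tolerance = 1e-6)
})

test_that("range normalization maps the training extremes to [-1, 1] and inverts", {
  nm <- fit_normalization(c(0, 5, 10))
  expect_equal(apply_normalization(c(0, 5, 10), nm), c(-1, 0, 1))
  # a test value outside the training range extends linearly past the band
  expect_equal(apply_normalization(12, nm), 1.4)
  x <- rnorm(50)
  nm2 <- fit_normalization(x)
  expect_equal(invert_normalization(apply_normalization(x, nm2), nm2), x,
               tolerance = 1e-12)
  expect_error(fit_normalization(rep(3, 10)), "constant")
})

test_that("training started at the generating parameters stays at zero loss", {
  set.seed(3)
  lags <- tiny_lags()
  truth <- draw_hnn_params(lags, seed = 6)
  R <- matrix(runif(400 * n_regressors(lags), -1, 1), 400)
  tgt <- hnn_forward(R, truth)
  fit <- train_scg(R, tgt, lags, config = quick_train(iters = 50, restarts = 1),
                   init = truth)
  expect_lt(fit$history[1], 1e-28)
  expect_lt(fit$loss, 1e-28)
})

test_that("accepted-step loss history is monotone non-increasing", {
  set.seed(14)
  lags <- tiny_lags()
  R <- matrix(runif(300 * n_regressors(lags), -1, 1), 300)
  tgt <- hnn_forward(R, draw_hnn_params(lags, seed = 1)) + rnorm(300, sd = 0.05)
  fit <- train_scg(R, tgt, lags, config = quick_train(iters = 200, restarts = 2))
  expect_true(all(diff(fit$history) <= 1e-15))
})

test_that("noiseless teacher-forced fit recovers the map: held-out one-step VAF >= 99%", {
  set.seed(31)
  lags <- tiny_lags()
  truth <- draw_hnn_params(lags, seed = 9)
  n <- 900
  R <- matrix(runif(n * n_regressors(lags), -1, 1), n)
  tgt <- hnn_forward(R, truth)
  train_idx <- 1:700
  fit <- train_scg(R[train_idx, ], tgt[train_idx], lags,
                   config = quick_train(iters = 500, restarts = 3))
  pred <- hnn_forward(R[-train_idx, ], fit$params)
  expect_gte(vaf(pred, tgt[-train_idx]), 99)
})

test_that("training warns when rows are scarce relative to parameters", {
  lags <- tiny_lags()
  R <- matrix(runif(30 * n_regressors(lags)), 30)
  expect_warning(
    train_scg(R, rnorm(30), lags, config = quick_train(iters = 5, restarts = 1)),
    "parameter")
})

test_that("network parameters round-trip exactly through key-value text", {
  par <- draw_hnn_params(study_lags(), seed = 17)
  path <- withr::local_tempfile()
  write_hnn_params(par, path)
  back <- read_hnn_params(path)
  expect_equal(narmaxhnn:::flatten_params(back),
               narmaxhnn:::flatten_params(par), tolerance = 0)
  expect_identical(back$lags, par$lags)
  expect_equal(back$sigmoid_2$rho, 1.6)
})
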