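test_that("lag structure implies the documented column count and burn-in", {
  lags <- study_lags()
  expect_identical(n_regressors(lags), 14L)
  expect_identical(burn_in(lags), 10L)
  expect_error(lag_spec(d1 = 8, d2 = 4), "d1 must not exceed d2")
  expect_error(lag_spec(d1 = -1), "non-negative")
})

test_that("regressor rows hold exactly the lagged values, with labeled columns", {
  lags <- study_lags()
  n <- 40L
  set.seed(1)
  p <- rnorm(n); v <- rnorm(n); y <- rnorm(n)
  R <- build_regressors(p, v, y, lags)
  expect_identical(ncol(R), 14L)
  expect_identical(nrow(R), n - 10L)
  expect_identical(attr(R, "first_index"), 10L)
  # spot-check a row: time k = 15 is row 5
  k <- 15
  expect_equal(unname(R[5, ]),
               c(v[k - 4:6], p[k - 4:6], p[k - 8:10], y[k - 1:5]))
  expect_identical(colnames(R)[1], "v[k-4]")
  expect_identical(colnames(R)[14], "y[k-5]")

  # constant signals give all-constant columns
  Rc <- build_regressors(rep(1, 20), rep(1, 20), rep(1, 20), lags)
  expect_true(all(Rc == 1))

  # ramp example with minimal lags: row at k=3 is [v(2), p(2), p(1), y(2)]
  lg <- lag_spec(d1 = 1, n1 = 0, d2 = 2, n2 = 0, ny = 1)
  ramp <- 0:9
  Rr <- build_regressors(ramp, 10 + ramp, 20 + ramp, lg)
  expect_equal(unname(Rr[1, ]), c(10 + ramp[2], ramp[2], ramp[1], 20 + ramp[2]))
})

test_that("regressor construction rejects misaligned or too-short signals", {
  lags <- study_lags()
  expect_error(build_regressors(1:10, 1:9, 1:10, lags), "same length")
  expect_error(build_regressors(1:10, 1:10, 1:10, lags), "too short")
})

test_that("term enumeration counts follow the multiset formula", {
  lags <- study_lags()
  # all monomials up to degree d over m columns (plus constant):
  # choose(m + d, d)
  expect_length(enumerate_terms(lags, 2, "narmax"), choose(14 + 2, 2))
  expect_length(enumerate_terms(lags, 1, "narmax"), 15)
  expect_length(enumerate_terms(lags, 3, "narmax"), choose(17, 3))
  expect_length(enumerate_terms(lags, 2, "volterra"), choose(9 + 2, 2))
  lg <- tiny_lags()
  m <- n_regressors(lg)
  expect_length(enumerate_terms(lg, 2), choose(m + 2, 2))
})

test_that("volterra enumeration contains no feedback-lag factor", {
  lags <- study_lags()
  ycols <- 10:14                      # y-lag columns in the regressor layout
  terms <- enumerate_terms(lags, 2, "volterra")
  expect_false(any(vapply(terms, function(t) any(t %in% ycols), TRUE)))
  # narmax enumeration does use them
  terms_n <- enumerate_terms(lags, 2, "narmax")
  expect_true(any(vapply(terms_n, function(t) any(t %in% ycols), TRUE)))
})

test_that("OFR recovers a two-term NARX system exactly, matching least squares", {
  sim <- toy_narx()
  lags <- lag_spec(d1 = 1, d2 = 1, n1 = 1, n2 = 1, ny = 2)
  R <- build_regressors(sim$u, numeric(length(sim$u)), sim$y, lags)
  tgt <- sim$y[(burn_in(lags) + 1):length(sim$y)]
  terms <- enumerate_terms(lags, 2, "narmax")
  Cm <- narmaxhnn:::term_matrix(terms, R)
  sel <- ofr_select(Cm, tgt, budget = 10, tol = 1e-12)
  expect_setequal(sel$labels, c("p[k-1]", "y[k-1]"))
  expect_gte(sum(sel$err), 0.999999)
  # independent oracle: ordinary least squares on the true two-term design
  ols <- lm(tgt ~ 0 + R[, "p[k-1]"] + R[, "y[k-1]"])
  truth <- unname(coef(ols))
  got <- sel$coefficients[match(c("p[k-1]", "y[k-1]"), sel$labels)]
  expect_equal(got, truth, tolerance = 1e-6)
  expect_equal(got, c(0.8, 0.5), tolerance = 1e-6)
})

test_that("OFR selects all true terms of a three-term nonlinear system first", {
  set.seed(9)
  n <- 600
  u <- runif(n, -1, 1)
  y <- numeric(n)
  for (k in 3:n) y[k] <- 0.5 * y[k - 1] + u[k - 2] + 0.1 * u[k - 1]^2
  lags <- lag_spec(d1 = 1, d2 = 1, n1 = 1, n2 = 1, ny = 2)
  R <- build_regressors(u, numeric(n), y, lags)
  tgt <- y[(burn_in(lags) + 1):n]
  Cm <- narmaxhnn:::term_matrix(enumerate_terms(lags, 2), R)
  sel <- ofr_select(Cm, tgt, budget = 3, tol = 1e-12)
  expect_setequal(sel$labels, c("y[k-1]", "p[k-2]", "p[k-1]*p[k-1]"))
  expect_gte(sum(sel$err), 0.999999)
})

test_that("ERR values are non-negative with bounded non-decreasing cumulative sum", {
  set.seed(21)
  for (trial in 1:5) {
    X <- matrix(rnorm(200 * 12), 200)
    yv <- rnorm(200)
    sel <- ofr_select(X, yv, budget = 8, tol = 0)
    expect_true(all(sel$err >= 0))
    cs <- cumsum(sel$err)
    expect_true(all(diff(cs) >= -1e-12))
    expect_lte(max(cs), 1 + 1e-10)
  }
})

test_that("a candidate orthogonal to the target has zero ERR and is never preferred", {
  set.seed(4)
  yv <- rnorm(300)
  ortho <- residuals(lm(rnorm(300) ~ yv))       # orthogonal to target by
  informative <- yv + 0.01 * rnorm(300)         # construction
  sel <- ofr_select(cbind(a = ortho, b = informative), yv,
                    budget = 1, tol = 0)
  expect_identical(sel$labels, "b")
  # direct ERR of the orthogonal column is (numerically) zero
  err_a <- sum(yv * ortho)^2 / (sum(ortho^2) * sum(yv^2))
  expect_lt(err_a, 1e-20)
})

test_that("OFR rejects a zero-variance target and skips collapsed candidates", {
  X <- matrix(rnorm(100 * 3), 100)
  expect_error(ofr_select(X, rep(2, 100), budget = 2), "zero variance")
  # duplicated column collapses after orthogonalization and is skipped
  set.seed(5)
  a <- rnorm(100); yv <- a + rnorm(100, sd = 0.1)
  sel <- ofr_select(cbind(a = a, dup = a, b = rnorm(100)), yv, budget = 3,
                    tol = 0)
  expect_true(2 %in% sel$skipped)
  expect_false("dup" %in% sel$labels)
})

test_that("a fitted volterra model is input-only: predictions ignore the output series", {
  exp <- tiny_experiment(seed = 13, n_trials = 2, duration = 6)
  tr <- exp$participants[[1]]$trials[[1]]
  lags <- study_lags()
  m <- fit_poly_model(tr$p, tr$v, tr$y, lags, kind = "volterra",
                      budget = 12, tol = 1e-6)
  expect_false(any(grepl("^y\\[", unlist(strsplit(m$labels, "*", fixed = TRUE)))))
  y_alt <- nh_signal(rev(tr$y$samples), rate = tr$y$rate)
  r1 <- predict_osa(m, tr$p, tr$v, tr$y)
  r2 <- predict_osa(m, tr$p, tr$v, y_alt)
  expect_identical(r1$predicted, r2$predicted)
})

test_that("poly model tables round-trip through delimited text", {
  sim <- toy_narx(300)
  lags <- lag_spec(d1 = 1, d2 = 1, n1 = 0, n2 = 0, ny = 1)
  m <- fit_poly_model(sim$u, numeric(300), sim$y, lags, kind = "narmax",
                      budget = 5, tol = 1e-10)
  path <- withr::local_tempfile()
  write_poly_table(m, path)
  df <- read_poly_table(path)
  expect_identical(df$term, m$labels)
  expect_equal(df$coefficient, m$coefficients, tolerance = 1e-15)
  expect_equal(df$ERR, m$err, tolerance = 1e-15)
})
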