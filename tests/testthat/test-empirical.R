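make_session <- function(data, dt = 2) ts_session(data, dt = dt)

test_that("bandpass keeps the passband and removes DC and fast components", {
  t_s <- seq(0, by = 2, length.out = 600)
  const <- make_session(matrix(5, 600, 1))
  out <- bandpass_filter(const)
  expect_lt(max(abs(out$data)), 1e-8)

  resp <- function(f_hz) {
    x <- sin(2 * pi * f_hz * t_s)
    y <- bandpass_filter(make_session(matrix(x, ncol = 1)))$data[, 1]
    # steady-state amplitude away from the edges
    core <- 150:450
    max(abs(y[core])) / max(abs(x[core]))
  }
  expect_gt(resp(0.055), 0.8)   # inside the 0.04-0.07 Hz band
  expect_lt(resp(0.2), 0.1)     # well outside
  expect_lt(abs(mean(bandpass_filter(make_session(
    matrix(rnorm(600), ncol = 1)))$data)), 1e-8)
})

test_that("bandpass rejects invalid bands and too-short sessions", {
  s <- make_session(matrix(rnorm(300), ncol = 1))
  expect_error(bandpass_filter(s, 0.04, 0.4), "Nyquist")
  expect_error(bandpass_filter(s, 0, 0.07), "band")
  expect_error(bandpass_filter(make_session(matrix(rnorm(15), ncol = 1))),
               "too short")
})

test_that("filtering concentrates spectral power (variance decreases)", {
  set.seed(2)
  s <- make_session(matrix(rnorm(2000), ncol = 2))
  before <- diag(empirical_covariances(s)$fc0)
  after <- diag(empirical_covariances(bandpass_filter(s))$fc0)
  expect_true(all(after < before))
})

test_that("lagged covariance follows a constructed shift", {
  set.seed(1)
  x <- rnorm(1001)
  s <- make_session(cbind(a = x[-1], b = x[-length(x)]))  # b lags a by 1
  cp <- empirical_covariances(s, lag = 1)
  # node b at t+1 equals node a at t: fc1[a, b] ~ var(a)
  expect_equal(cp$fc1[1, 2], cp$fc0[1, 1], tolerance = 0.02)
  # fc1[b, a] ~ autocovariance of white noise at 2 samples ~ 0
  expect_lt(abs(cp$fc1[2, 1]), 0.05)
  expect_identical(cp$fc0, t(cp$fc0))
})

test_that("independent white noise has near-zero lagged covariance", {
  set.seed(3)
  Tn <- 1e4
  s <- make_session(matrix(rnorm(Tn * 3), ncol = 3))
  cp <- empirical_covariances(s, lag = 1)
  off <- cp$fc1[row(cp$fc1) != col(cp$fc1)]
  expect_lt(max(abs(off)), 5 / sqrt(Tn))
})

test_that("covariance estimation guards its preconditions", {
  s <- make_session(matrix(rnorm(30), ncol = 2))
  expect_error(empirical_covariances(s, lag = 0.5), "integer")
  expect_error(empirical_covariances(s, lag = 28), "too short")
  s2 <- make_session(cbind(rnorm(50), 1))
  expect_warning(empirical_covariances(s2, 1), "zero-variance")
})

test_that("empirical covariances of simulated MOU data converge to the model", {
  rs <- random_stable_params(6, seed = 21)
  mc <- model_covariances(rs$params, lag = 1)
  s <- simulate_mou(rs$params, 4e4, 0.05, 20, seed = 5)
  cp <- empirical_covariances(s, lag = 1)
  rel <- function(emp, mod) norm(emp - mod, "F") / norm(mod, "F")
  expect_lt(rel(cp$fc0, mc$fc0), 0.1)
  expect_lt(rel(cp$fc1, mc$fc1), 0.15)
})

test_that("tau estimation inverts an exact exponential decay", {
  tau <- estimate_tau(c(1, exp(-0.5), exp(-1)))
  expect_equal(as.numeric(tau), 2, tolerance = 1e-10)
  expect_false(attr(tau, "fallback"))

  flat <- estimate_tau(c(1, 1, 1), tau_default = 1.5)
  expect_true(attr(flat, "fallback"))
  expect_equal(as.numeric(flat), 1.5)
  neg <- estimate_tau(c(1, -0.1, 0.5), tau_default = 2)
  expect_true(attr(neg, "fallback"))
  expect_error(estimate_tau(c(-1, 0.5, 0.2)), "positive")
})

test_that("tau is recovered from uncoupled simulated data", {
  p <- mou_params(matrix(0, 5, 5), 1, 2)
  s <- simulate_mou(p, 1e4, 0.05, 20, seed = 8)  # sampled at dt = tau/2
  tau_hat <- estimate_tau(session_mean_autocov(s, 2)) * s$dt
  expect_lt(abs(as.numeric(tau_hat) - 2) / 2, 0.15)
})
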