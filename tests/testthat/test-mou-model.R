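test_that("parameter validation enforces the model invariants", {
  expect_error(mou_params(matrix(0, 2, 3), 1, 1), "square")
  ec <- matrix(0, 2, 2); diag(ec) <- 0.1
  expect_error(mou_params(ec, 1, 1), "diagonal")
  ec <- matrix(c(0, -0.1, 0, 0), 2, 2)
  expect_error(mou_params(ec, 1, 1), ">= 0")
  expect_error(mou_params(matrix(0, 2, 2), 1, -1), "tau_x")
  expect_error(mou_params(matrix(0, 2, 2), 0, 1), "sigma")
})

test_that("state matrix follows A = -I/tau + t(ec) and reports stability", {
  A <- build_state_matrix(mou_params(matrix(0, 2, 2), 1, 1))
  expect_equal(unclass(A), -diag(2), ignore_attr = TRUE)

  ec <- matrix(0, 2, 2); ec[1, 2] <- 0.3  # link 1 -> 2
  A <- build_state_matrix(mou_params(ec, 1, 2))
  expect_equal(unclass(A)[2, 1], 0.3)  # target row, source column
  expect_equal(unclass(A)[1, 2], 0)
  expect_equal(diag(A), rep(-0.5, 2))
  expect_equal(attr(A, "max_re_eig"), -0.5)

  rs <- random_stable_params(10, seed = 3)
  A <- build_state_matrix(rs$params)
  expect_lt(attr(A, "max_re_eig"), 0)
  expect_equal(attr(A, "max_re_eig"),
               max(Re(eigen(unclass(A), only.values = TRUE)$values)))
})

test_that("model covariances match the uncoupled closed form", {
  # dx = -x/tau dt + dB: stationary var = sigma * tau / 2, autocov decays e^(-lag/tau)
  p <- mou_params(matrix(0, 4, 4), 2, 1)
  mc <- model_covariances(p, lag = 1)
  expect_equal(mc$fc0, diag(4), tolerance = 1e-10)
  expect_equal(mc$fc1, exp(-1) * diag(4), tolerance = 1e-10)

  p2 <- mou_params(matrix(0, 3, 3), c(1, 2, 3), 4)
  mc2 <- model_covariances(p2, lag = 2)
  expect_equal(diag(mc2$fc0), c(1, 2, 3) * 4 / 2, tolerance = 1e-10)
  expect_equal(mc2$fc1, mc2$fc0 * exp(-2 / 4), tolerance = 1e-10)
})

test_that("Lyapunov covariances agree with vectorization and integral oracles", {
  ec <- matrix(0, 3, 3); ec[1, 2] <- 0.4
  p <- mou_params(ec, c(1, 0.5, 2), 1)
  A <- unclass(build_state_matrix(p))
  mc <- model_covariances(p, lag = 1)
  expect_equal(mc$fc0, lyap_kron(A, diag(p$sigma)), tolerance = 1e-10)
  expect_equal(mc$fc0, lyap_integral(A, diag(p$sigma)), tolerance = 1e-4)
  expect_equal(mc$fc1, mc$fc0 %*% as.matrix(Matrix::expm(t(A))),
               tolerance = 1e-8)

  rs <- random_stable_params(8, seed = 11)
  mc <- model_covariances(rs$params, lag = 1)
  A <- unclass(build_state_matrix(rs$params))
  expect_equal(mc$fc0, lyap_kron(A, diag(rs$params$sigma)), tolerance = 1e-9)
  # symmetric positive semi-definite
  expect_equal(mc$fc0, t(mc$fc0), tolerance = 1e-8)
  expect_gt(min(eigen(mc$fc0, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("a single directed link induces forward-lag asymmetry", {
  ec <- matrix(0, 3, 3); ec[1, 2] <- 0.4  # 1 -> 2
  mc <- model_covariances(mou_params(ec, 1, 1), lag = 1)
  expect_gt(mc$fc1[1, 2], mc$fc1[2, 1])
})

test_that("unstable or malformed inputs are rejected", {
  ec <- matrix(0, 2, 2); ec[1, 2] <- ec[2, 1] <- 2  # coupling beats decay
  p <- mou_params(ec, 1, 1)
  expect_error(model_covariances(p, 1), "unstable")
  expect_error(model_covariances(mou_params(matrix(0, 2, 2), 1, 1), lag = 0),
               "lag")
})

test_that("simulation is seed-reproducible and respects the step bound", {
  p <- mou_params(matrix(0, 3, 3), 2, 1)
  s1 <- simulate_mou(p, 50, 0.05, 2, seed = 9)
  s2 <- simulate_mou(p, 50, 0.05, 2, seed = 9)
  expect_identical(s1$data, s2$data)
  expect_equal(s1$dt, 0.1)
  expect_error(simulate_mou(p, 10, dt_integration = 0.5), "dt_integration")
})

test_that("long simulations reproduce the stationary variance", {
  p <- mou_params(matrix(0, 2, 2), 2, 1)
  s <- simulate_mou(p, 1e4, 0.02, 25, seed = 4)  # output every 0.5 tau
  v <- apply(s$data, 2, var)
  expect_true(all(abs(v - 1) < 0.05))
})
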