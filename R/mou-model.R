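#' Multivariate Ornstein-Uhlenbeck model parameters
#'
#' Bundles the parameters of the linear stochastic network model
#' \deqn{dx_i = \left(-x_i/\tau_x + \sum_{j \ne i} C_{ij}\, x_j\right) dt + dB_i,}
#' where `ec` holds the directed coupling weights (effective connectivity),
#' `sigma` the variances of the independent node-wise noise inputs, and
#' `tau_x` the shared exponential decay time constant.
#'
#' The coupling matrix is stored source-row by target-column: `ec[i, j]` is
#' the weight of the directed link from node `i` to node `j`, so the drift on
#' node `i` receives `sum_j ec[j, i] * x_j` and the state matrix is
#' `A = -I/tau_x + t(ec)`.
#'
#' @param ec square numeric matrix of nonnegative directed weights with zero
#'   diagonal; `ec[i, j]` is the strength of the link `i -> j` (units 1/time).
#' @param sigma numeric vector of per-node input variance rates, all
#'   `>= sigma_min`; recycled to the number of nodes if scalar.
#' @param tau_x positive scalar time constant, in the same time unit as the
#'   sampling period of the data the model is fitted to (seconds here).
#' @param sigma_min smallest admissible input variance.
#' @return An object of class `mou_params` with fields `ec`, `sigma`,
#'   `tau_x`, `n_nodes`.
#' @examples
#' p <- mou_params(ec = matrix(0, 3, 3), sigma = 2, tau_x = 1)
#' model_covariances(p, lag = 1)$fc0  # identity: stationary var sigma*tau/2
#' @export
mou_params <- function(ec, sigma, tau_x, sigma_min = 1e-6) {
  stop_if(!is_square(ec), "`ec` must be a square matrix")
  n <- nrow(ec)
  stop_if(any(diag(ec) != 0), "diagonal of `ec` must be exactly 0")
  stop_if(any(ec < 0), "`ec` entries must be >= 0")
  if (length(sigma) == 1L) sigma <- rep(sigma, n)
  stop_if(length(sigma) != n, "`sigma` must have one entry per node")
  stop_if(any(sigma < sigma_min), "all `sigma` must be >= sigma_min (%g)", sigma_min)
  stop_if(!is.numeric(tau_x) || length(tau_x) != 1L || tau_x <= 0,
          "`tau_x` must be a positive scalar")
  structure(list(ec = unname(ec), sigma = as.numeric(sigma),
                 tau_x = tau_x, n_nodes = n),
            class = "mou_params")
}

#' @export
print.mou_params <- function(x, ...) {
  A <- build_state_matrix(x)
  cat(sprintf("MOU parameters: %d nodes, tau_x = %g, %d nonzero links, max Re(eig) = %.4f\n",
              x$n_nodes, x$tau_x, sum(x$ec > 0), attr(A, "max_re_eig")))
  invisible(x)
}

#' State (Jacobian) matrix of the MOU system
#'
#' Builds `A = -I/tau_x + t(ec)`, so that `dx = A x dt + dB` reproduces the
#' model dynamics, and reports the stability margin (maximum real part of the
#' eigenvalues) as attribute `max_re_eig`. The system is stationary iff that
#' margin is negative.
#'
#' @param params a [mou_params] object.
#' @return The state matrix, with attribute `max_re_eig`.
#' @export
build_state_matrix <- function(params) {
  stopifnot(inherits(params, "mou_params"))
  A <- t(params$ec)
  diag(A) <- diag(A) - 1 / params$tau_x
  attr(A, "max_re_eig") <- cpp_max_re_eig(A)
  A
}

#' Covariance pair (zero-lag and lagged spatial covariance)
#'
#' Container for FC0 (covariance without lag, symmetric) and FC1 (covariance
#' with lag: `fc1[i, j]` = covariance of node `i` at time `t` with node `j`
#' at time `t + lag`). FC1 is in general asymmetric; its asymmetry carries
#' the directed information the model fit exploits.
#'
#' @param fc0 symmetric matrix (to tolerance `tol`).
#' @param fc1 matrix of the same size.
#' @param lag positive lag, in time samples.
#' @param tol symmetry tolerance for `fc0`.
#' @return An object of class `cov_pair`.
#' @export
cov_pair <- function(fc0, fc1, lag, tol = 1e-8) {
  stop_if(!is_square(fc0) || !is_square(fc1) || nrow(fc0) != nrow(fc1),
          "`fc0` and `fc1` must be square matrices of equal size")
  stop_if(max(abs(fc0 - t(fc0))) > tol * max(1, max(abs(fc0))),
          "`fc0` must be symmetric to tolerance")
  stop_if(any(diag(fc0) < 0), "`fc0` diagonal must be >= 0")
  stop_if(!is.numeric(lag) || length(lag) != 1L || lag <= 0,
          "`lag` must be a positive scalar")
  structure(list(fc0 = unname((fc0 + t(fc0)) / 2), fc1 = unname(fc1), lag = lag),
            class = "cov_pair")
}

#' Model covariances of a stationary MOU process
#'
#' Computes the theoretical spatial covariances of the model: FC0 solves the
#' continuous-time Lyapunov equation `A Q0 + Q0 A' + diag(sigma) = 0`, and
#' the lagged covariance is `FC1 = Q0 expm(A' lag)`. These are the
#' quantities the estimation procedure matches to their empirical
#' counterparts.
#'
#' @param params a [mou_params] object; the state matrix must be stable.
#' @param lag positive lag in time samples (same unit as `tau_x`).
#' @return A [cov_pair].
#' @export
model_covariances <- function(params, lag) {
  stopifnot(inherits(params, "mou_params"))
  stop_if(!is.numeric(lag) || length(lag) != 1L || lag <= 0,
          "`lag` must be a positive scalar")
  A <- build_state_matrix(params)
  stop_if(attr(A, "max_re_eig") >= 0,
          "state matrix is unstable (max Re(eig) = %.4g); the model has no stationary covariance",
          attr(A, "max_re_eig"))
  q <- cpp_model_cov(params$ec, params$sigma, params$tau_x, lag)
  cov_pair((q$fc0 + t(q$fc0)) / 2, q$fc1, lag)
}

#' One session of ROI time series
#'
#' @param data numeric matrix, time points in rows and nodes (ROIs) in
#'   columns; no missing values, at least 3 time points.
#' @param dt sampling period in seconds (the TR for fMRI sessions).
#' @param node_labels character vector of ROI names, one per column.
#' @param subject_id,group,condition identifiers attached to the session.
#' @return An object of class `ts_session`.
#' @export
ts_session <- function(data, dt, node_labels = colnames(data),
                       subject_id = NA_character_, group = NA_character_,
                       condition = NA_character_) {
  data <- as.matrix(data)
  stop_if(!is.numeric(data), "`data` must be numeric")
  stop_if(anyNA(data), "`data` contains missing values")
  stop_if(nrow(data) < 3, "a session needs at least 3 time points")
  stop_if(!is.numeric(dt) || length(dt) != 1L || dt <= 0,
          "`dt` must be a positive scalar")
  if (is.null(node_labels)) node_labels <- paste0("ROI_", seq_len(ncol(data)))
  stop_if(length(node_labels) != ncol(data),
          "`node_labels` must have one entry per column (%d != %d)",
          length(node_labels), ncol(data))
  structure(list(data = unname(data), dt = dt,
                 node_labels = as.character(node_labels),
                 subject_id = subject_id, group = group, condition = condition),
            class = "ts_session")
}

#' @export
print.ts_session <- function(x, ...) {
  cat(sprintf("ts_session: %d time points x %d ROIs, dt = %gs [subject=%s group=%s condition=%s]\n",
              nrow(x$data), ncol(x$data), x$dt, x$subject_id, x$group, x$condition))
  invisible(x)
}

#' Simulate a MOU trajectory (Euler-Maruyama)
#'
#' Forward generator for the model: integrates the linear SDE with the
#' Euler-Maruyama scheme from a burn-in of at least `10 * tau_x`, then
#' returns `n_samples` rows taken every `subsample` integration steps, so
#' the output sampling period is `dt_integration * subsample`.
#'
#' @param params a stable [mou_params] object.
#' @param n_samples number of output time points.
#' @param dt_integration integration step; must be `<= tau_x / 10`
#'   (default `0.05 * tau_x`).
#' @param subsample keep every `subsample`-th integration step.
#' @param seed integer seed; runs are reproducible given the seed.
#' @param subject_id,group,condition identifiers for the returned session.
#' @return A [ts_session] with `dt = dt_integration * subsample`.
#' @export
simulate_mou <- function(params, n_samples, dt_integration = 0.05 * params$tau_x,
                         subsample = 1L, seed = 1L,
                         subject_id = NA_character_, group = NA_character_,
                         condition = NA_character_) {
  stopifnot(inherits(params, "mou_params"))
  stop_if(dt_integration > params$tau_x / 10 + 1e-12,
          "`dt_integration` must be <= tau_x / 10 for a faithful integration")
  A <- build_state_matrix(params)
  stop_if(attr(A, "max_re_eig") >= 0, "unstable parameters: cannot simulate")
  n <- params$n_nodes
  dt <- dt_integration
  n_burn <- ceiling(10 * params$tau_x / dt)
  n_steps <- n_burn + n_samples * subsample
  set.seed(seed)
  noise_sd <- sqrt(params$sigma * dt)
  out <- matrix(0, n_samples, n)
  x <- numeric(n)
  tA <- t(A)  # row vector update: x <- x + dt * x %*% t(A) + noise
  k <- 0L
  for (s in seq_len(n_steps)) {
    x <- x + dt * drop(x %*% tA) + rnorm(n) * noise_sd
    if (s > n_burn && (s - n_burn) %% subsample == 0L) {
      k <- k + 1L
      out[k, ] <- x
    }
    if (s %% 1000L == 0L && sqrt(sum(x^2)) > 1e8)
      stop("trajectory norm diverged during integration", call. = FALSE)
  }
  ts_session(out, dt = dt * subsample,
             node_labels = paste0("ROI_", seq_len(n)),
             subject_id = subject_id, group = group, condition = condition)
}
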