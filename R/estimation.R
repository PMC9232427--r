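#' Estimate the decay time constant from autocovariances
#'
#' The MOU autocovariance decays as `exp(-lag / tau_x)`, so the time
#' constant is estimated as minus the inverse slope of a linear regression
#' of `log(mean autocovariance)` on lag over lags `0..L`. If the fitted
#' slope is nonnegative, or any used autocovariance is nonpositive, the
#' fallback value is returned and flagged via the `fallback` attribute.
#'
#' @param autocov numeric vector of mean autocovariance at lags `0..L`
#'   (`L >= 2`), e.g. from [session_mean_autocov]. Lags are in samples;
#'   multiply by the sampling period for seconds.
#' @param tau_default fallback time constant.
#' @return Estimated tau (same unit as the lag spacing), with attribute
#'   `fallback` (logical).
#' @export
estimate_tau <- function(autocov, tau_default = 1) {
  stop_if(length(autocov) < 3, "need autocovariances at lags 0..L with L >= 2")
  stop_if(autocov[1] <= 0, "autocovariance at lag 0 must be positive")
  lags <- seq_along(autocov) - 1
  if (any(autocov <= 0)) {
    tau <- tau_default
    attr(tau, "fallback") <- TRUE
    return(tau)
  }
  slope <- unname(coef(lm(log(autocov) ~ lags))[2])
  if (slope >= 0) {
    tau <- tau_default
    attr(tau, "fallback") <- TRUE
    return(tau)
  }
  tau <- -1 / slope
  attr(tau, "fallback") <- FALSE
  tau
}

#' Fit settings for the EC estimation
#'
#' Defaults of the iterative gradient descent: learning rates for the EC
#' weights (`eps_c`) and input variances (`eps_sigma`), iteration cap, early
#' stopping (stop when the model error fails to improve by `tol_improve`
#' for `patience` iterations), the variance floor, the stability margin a
#' candidate step must respect, and the conditioning limit beyond which the
#' Lyapunov covariance is inverted by pseudo-inverse.
#'
#' @param eps_c,eps_sigma learning rates.
#' @param max_iter iteration cap.
#' @param tol_improve,patience early-stopping rule.
#' @param sigma_min variance floor.
#' @param stab_margin required `-max Re(eig)` of the state matrix.
#' @param cond_max conditioning limit for plain inversion of Q0.
#' @return A list of settings.
#' @export
fit_config <- function(eps_c = 5e-4, eps_sigma = 0.05, max_iter = 10000L,
                       tol_improve = 1e-5, patience = 20L, sigma_min = 1e-6,
                       stab_margin = 1e-6, cond_max = 1e10) {
  list(eps_c = eps_c, eps_sigma = eps_sigma, max_iter = as.integer(max_iter),
       tol_improve = tol_improve, patience = as.integer(patience),
       sigma_min = sigma_min, stab_margin = stab_margin, cond_max = cond_max)
}

#' Fit masked MOU effective connectivity to empirical covariances
#'
#' Iterative gradient-descent estimation of the directed EC weights and
#' node-wise input variances so the model covariances reproduce the
#' empirical FC0/FC1 pair. At each iteration the model covariances are
#' obtained from the Lyapunov equation, the state-matrix increment is
#' `dA = t(solve(Q0, D0 + D1 expm(-A' lag)))` with `D0, D1` the covariance
#' residuals, EC is incremented by `eps_c * t(dA)` restricted to the mask
#' and clipped at 0, and the variances by `-eps_sigma * diag(A' D0 + D0 A)`
#' floored at `sigma_min`. Steps that would destabilize the system are
#' rejected and the learning rates halved. The returned parameters are
#' those of the best-error iteration.
#'
#' The model error is
#' `E = (|FC0 - Q0|_F / |FC0|_F + |FC1 - Q1|_F / |FC1|_F) / 2`, and the
#' Pearson correlations between vectorized model and empirical matrices are
#' tracked alongside.
#'
#' @param empirical a [cov_pair] of empirical covariances (fc0 positive
#'   semi-definite after symmetrization).
#' @param mask a [conn_mask]; EC is exactly 0 outside the mask and on the
#'   diagonal.
#' @param tau_x time constant (e.g. from [estimate_tau]), in the unit of
#'   the lag.
#' @param config settings from [fit_config].
#' @return An object of class `mou_fit`: `params` ([mou_params]), `trace`
#'   (per-iteration data frame: `iter`, `error`, `pearson_fc0`,
#'   `pearson_fc1`, `eps_c`, `eps_sigma`), `best_iter`, `best_error`,
#'   `n_rejected`, `used_pinv`.
#' @export
fit_mou_ec <- function(empirical, mask, tau_x, config = fit_config()) {
  stopifnot(inherits(empirical, "cov_pair"), inherits(mask, "conn_mask"))
  stop_if(mask$density <= 0, "mask density must be > 0")
  stop_if(nrow(empirical$fc0) != mask$n_nodes,
          "covariances (%d nodes) and mask (%d nodes) disagree",
          nrow(empirical$fc0), mask$n_nodes)
  ev_min <- min(eigen((empirical$fc0 + t(empirical$fc0)) / 2,
                      symmetric = TRUE, only.values = TRUE)$values)
  stop_if(ev_min < -1e-8 * max(abs(empirical$fc0)),
          "empirical fc0 is not positive semi-definite (min eigenvalue %.3g)", ev_min)
  fit <- cpp_fit_mou(empirical$fc0, empirical$fc1, mask$mask,
                     tau_x, empirical$lag,
                     config$eps_c, config$eps_sigma, config$max_iter,
                     config$tol_improve, config$patience, config$sigma_min,
                     config$stab_margin, config$cond_max)
  trace <- as.data.frame(fit$trace)
  names(trace) <- c("error", "pearson_fc0", "pearson_fc1", "eps_c", "eps_sigma")
  trace <- cbind(iter = seq_len(nrow(trace)), trace)
  structure(list(
    params = mou_params(fit$ec, pmax(fit$sigma, config$sigma_min), tau_x,
                        sigma_min = config$sigma_min),
    trace = trace,
    best_iter = fit$best_iter,
    best_error = fit$best_error,
    n_rejected = fit$n_rejected,
    used_pinv = fit$used_pinv,
    lag = empirical$lag,
    mask = mask
  ), class = "mou_fit")
}

#' @export
print.mou_fit <- function(x, ...) {
  cat(sprintf("mou_fit: %d nodes, best E = %.4f at iter %d/%d (r_fc0 = %.3f, r_fc1 = %.3f)\n",
              x$params$n_nodes, x$best_error, x$best_iter, nrow(x$trace),
              x$trace$pearson_fc0[x$best_iter], x$trace$pearson_fc1[x$best_iter]))
  invisible(x)
}

#' Goodness of fit of MOU parameters to an empirical covariance pair
#'
#' Recomputes the model covariances at the given lag and returns the model
#' error `E` and the Pearson correlations between vectorized model and
#' empirical FC0/FC1. Deterministic; shares its computation with the fit
#' loop, so the error of the fitted parameters equals the best trace value.
#'
#' @param empirical a [cov_pair].
#' @param params a stable [mou_params].
#' @param lag the lag used in the fit.
#' @return List with `error`, `pearson_fc0`, `pearson_fc1`.
#' @export
fit_quality <- function(empirical, params, lag) {
  stopifnot(inherits(empirical, "cov_pair"), inherits(params, "mou_params"))
  A <- build_state_matrix(params)
  stop_if(attr(A, "max_re_eig") >= 0, "unstable parameters")
  cpp_fit_quality(params$ec, params$sigma, params$tau_x, lag,
                  empirical$fc0, empirical$fc1)
}
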