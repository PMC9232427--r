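#' Zero-phase narrowband filtering of a session
#'
#' Applies a 2nd-order Butterworth bandpass forward and backward
#' ([signal::filtfilt]) to each node's series, the common fMRI choice for
#' isolating the slow BOLD fluctuations (0.04-0.07 Hz in this pipeline)
#' without phase distortion. Each node is demeaned first; the passband
#' excludes DC, so outputs have (numerically) zero mean.
#'
#' @param session a [ts_session].
#' @param low_hz,high_hz band edges in Hz; `0 < low_hz < high_hz < ` Nyquist
#'   (`1 / (2 dt)`).
#' @param order Butterworth order (default 2).
#' @return The filtered [ts_session].
#' @export
bandpass_filter <- function(session, low_hz = 0.04, high_hz = 0.07, order = 2L) {
  stopifnot(inherits(session, "ts_session"))
  nyq <- 1 / (2 * session$dt)
  stop_if(!(low_hz > 0 && low_hz < high_hz && high_hz < nyq),
          "band must satisfy 0 < low (%g) < high (%g) < Nyquist (%g Hz)",
          low_hz, high_hz, nyq)
  stop_if(nrow(session$data) < 10 * order,
          "session too short (%d points) for filter edge effects (need >= %d)",
          nrow(session$data), 10 * order)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  x <- sweep(session$data, 2, colMeans(session$data))
  out <- apply(x, 2, function(col) signal::filtfilt(bf, col))
  # filtfilt leaves a small edge-effect offset; remove it exactly
  session$data <- sweep(out, 2, colMeans(out))
  session
}

#' Empirical zero-lag and lagged covariances of a session
#'
#' Demeans each node and computes
#' `fc0[i, j] = sum_t x_i(t) x_j(t) / (T - lag - 1)` and
#' `fc1[i, j] = sum_t x_i(t) x_j(t + lag) / (T - lag - 1)`, both sums over
#' `t = 1 .. T - lag`, so the two matrices average the same time points with
#' the same denominator. `fc0` is symmetrized by averaging with its
#' transpose.
#'
#' @param session a [ts_session].
#' @param lag positive integer lag in samples (default 1, i.e. one TR).
#' @return A [cov_pair]. A zero-variance (constant) node triggers a warning
#'   and the attribute `degenerate_nodes` on the result.
#' @export
empirical_covariances <- function(session, lag = 1L) {
  stopifnot(inherits(session, "ts_session"))
  stop_if(length(lag) != 1L || lag < 1 || lag != round(lag),
          "`lag` must be a positive integer number of samples")
  lag <- as.integer(lag)
  Tn <- nrow(session$data)
  stop_if(Tn <= lag + 2, "session too short (T = %d) for lag %d", Tn, lag)
  x <- sweep(session$data, 2, colMeans(session$data))
  degenerate <- which(apply(x, 2, function(v) all(v == 0)))
  if (length(degenerate))
    warning(sprintf("zero-variance node(s): %s",
                    paste(degenerate, collapse = ", ")), call. = FALSE)
  idx <- seq_len(Tn - lag)
  x0 <- x[idx, , drop = FALSE]
  x1 <- x[idx + lag, , drop = FALSE]
  denom <- Tn - lag - 1
  fc0 <- crossprod(x0) / denom
  fc1 <- crossprod(x0, x1) / denom
  out <- cov_pair((fc0 + t(fc0)) / 2, fc1, lag)
  if (length(degenerate)) attr(out, "degenerate_nodes") <- degenerate
  out
}

#' Mean autocovariance of a session over the first lags
#'
#' Averages the per-node autocovariance at lags `0..n_lags`, the input to
#' [estimate_tau].
#'
#' @param session a [ts_session].
#' @param n_lags largest lag (in samples), default 2.
#' @return Numeric vector of length `n_lags + 1`.
#' @export
session_mean_autocov <- function(session, n_lags = 2L) {
  stopifnot(inherits(session, "ts_session"))
  Tn <- nrow(session$data)
  stop_if(Tn <= n_lags + 2, "session too short for %d lags", n_lags)
  x <- sweep(session$data, 2, colMeans(session$data))
  vapply(0:n_lags, function(l) {
    idx <- seq_len(Tn - l)
    mean(colSums(x[idx, , drop = FALSE] * x[idx + l, , drop = FALSE]) / (Tn - l - 1))
  }, numeric(1))
}
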