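// Core linear-algebra kernels for the multivariate Ornstein-Uhlenbeck model:
// stationary (Lyapunov) covariances, lagged covariances, and the iterative
// gradient-descent fit of the connectivity weights under a structural mask.
// Kept in C++ because a whole-cohort fit performs thousands of Lyapunov
// solves and matrix exponentials per session.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Solve A Q + Q A' + S = 0 for Q (continuous-time Lyapunov equation).
// [[Rcpp::export]]
arma::mat cpp_lyap(const arma::mat& A, const arma::mat& S) {
  return syl(A, A.t(), S);
}

// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& M) {
  return expmat(M);
}

// Maximum real part of the eigenvalues of A (stability margin).
// [[Rcpp::export]]
double cpp_max_re_eig(const arma::mat& A) {
  cx_vec ev = eig_gen(A);
  return max(real(ev));
}

static mat state_matrix(const mat& ec, double tau_x) {
  // A[i][j] = -delta_ij / tau_x + ec[j][i]
  mat A = ec.t();
  A.diag() -= 1.0 / tau_x;
  return A;
}

// Model error E and Pearson correlations between model and empirical
// covariance pairs. Shared by the fit loop and fit_quality() so the two
// report bitwise-identical diagnostics.
static void cov_goodness(const mat& FC0, const mat& FC1,
                         const mat& Q0, const mat& Q1,
                         double& E, double& r0, double& r1) {
  double n0 = norm(FC0, "fro"), n1 = norm(FC1, "fro");
  E = 0.5 * (norm(FC0 - Q0, "fro") / n0 + norm(FC1 - Q1, "fro") / n1);
  r0 = as_scalar(cor(vectorise(Q0), vectorise(FC0)));
  r1 = as_scalar(cor(vectorise(Q1), vectorise(FC1)));
}

// [[Rcpp::export]]
Rcpp::List cpp_model_cov(const arma::mat& ec, const arma::vec& sigma,
                         double tau_x, double lag) {
  mat A = state_matrix(ec, tau_x);
  mat Q0 = syl(A, A.t(), mat(diagmat(sigma)));
  mat Q1 = Q0 * expmat(A.t() * lag);
  return Rcpp::List::create(Rcpp::Named("fc0") = Q0,
                            Rcpp::Named("fc1") = Q1);
}

// [[Rcpp::export]]
Rcpp::List cpp_fit_quality(const arma::mat& ec, const arma::vec& sigma,
                           double tau_x, double lag,
                           const arma::mat& FC0, const arma::mat& FC1) {
  mat A = state_matrix(ec, tau_x);
  mat Q0 = syl(A, A.t(), mat(diagmat(sigma)));
  mat Q1 = Q0 * expmat(A.t() * lag);
  double E, r0, r1;
  cov_goodness(FC0, FC1, Q0, Q1, E, r0, r1);
  return Rcpp::List::create(Rcpp::Named("error") = E,
                            Rcpp::Named("pearson_fc0") = r0,
                            Rcpp::Named("pearson_fc1") = r1);
}

// Gradient-descent estimation of masked EC weights and input variances.
// mask_dir is the directed admissibility matrix in source-row x target-column
// orientation (entry [i][j] = 1 allows the link i -> j).
// [[Rcpp::export]]
Rcpp::List cpp_fit_mou(const arma::mat& FC0, const arma::mat& FC1,
                       const arma::mat& mask_dir,
                       double tau_x, double lag,
                       double eps_C, double eps_S,
                       int max_iter, double tol_improve, int patience,
                       double sigma_min, double stab_margin,
                       double cond_max) {
  const uword n = FC0.n_rows;
  mat ec(n, n, fill::zeros);
  vec sigma(n, fill::ones);

  mat best_ec = ec;
  vec best_sigma = sigma;
  double best_E = datum::inf;
  int best_iter = 0, stall = 0, n_rejected = 0;
  bool used_pinv = false;

  mat trace(max_iter, 5, fill::value(datum::nan));
  int it = 0;

  mat expAtl_neg;  // expm(-A' * lag), reused in the update
  for (it = 0; it < max_iter; ++it) {
    mat A = state_matrix(ec, tau_x);
    mat Q0 = syl(A, A.t(), mat(diagmat(sigma)));
    if (!Q0.is_finite()) break;  // keep the best parameters seen so far
    mat Q1 = Q0 * expmat(A.t() * lag);

    double E, r0, r1;
    cov_goodness(FC0, FC1, Q0, Q1, E, r0, r1);
    trace(it, 0) = E; trace(it, 1) = r0; trace(it, 2) = r1;
    trace(it, 3) = eps_C; trace(it, 4) = eps_S;

    if (E < best_E - tol_improve) {
      stall = 0;
    } else {
      ++stall;
    }
    if (E < best_E) {
      best_E = E; best_ec = ec; best_sigma = sigma; best_iter = it;
    }
    if (stall >= patience) { ++it; break; }

    mat D0 = FC0 - Q0;
    mat D1 = FC1 - Q1;
    expAtl_neg = expmat(-A.t() * lag);
    mat rhs = D0 + D1 * expAtl_neg;
    mat dA;
    if (rcond(Q0) < 1.0 / cond_max) {
      mat Qi;
      if (!pinv(Qi, Q0)) break;
      dA = (Qi * rhs).t();
      used_pinv = true;
    } else {
      mat sol;
      if (!solve(sol, Q0, rhs)) break;
      dA = sol.t();
    }

    // candidate step, clipped to the admissible set at every iteration
    mat ec_new = ec + eps_C * dA.t();
    ec_new.elem(find(mask_dir == 0)).zeros();
    ec_new.elem(find(ec_new < 0)).zeros();
    ec_new.diag().zeros();
    mat sgrad = A.t() * D0 + D0 * A;
    vec dS = sgrad.diag();
    vec sigma_new = sigma - eps_S * dS;
    sigma_new.elem(find(sigma_new < sigma_min)).fill(sigma_min);

    if (cpp_max_re_eig(state_matrix(ec_new, tau_x)) > -stab_margin) {
      // step would destabilise the system: reject and halve the rates
      eps_C *= 0.5; eps_S *= 0.5;
      ++n_rejected;
      if (eps_C < 1e-12) { ++it; break; }
      continue;
    }
    ec = ec_new;
    sigma = sigma_new;
  }

  int n_used = std::min(it, max_iter);
  return Rcpp::List::create(
      Rcpp::Named("ec") = best_ec,
      Rcpp::Named("sigma") = best_sigma,
      Rcpp::Named("best_iter") = best_iter + 1,
      Rcpp::Named("best_error") = best_E,
      Rcpp::Named("n_iter") = n_used,
      Rcpp::Named("n_rejected") = n_rejected,
      Rcpp::Named("used_pinv") = used_pinv,
      Rcpp::Named("trace") = trace.rows(0, n_used - 1));
}
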