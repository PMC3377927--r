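#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// EM for a 16-component normal mixture with fixed, individual-specific
// weights (the conditional QTL-genotype probabilities).  Optionally
// maximizes under a single linear constraint c'u = 0 on the component
// means via the exact Lagrange solution of the weighted least-squares
// M-step.  Classes whose posterior mass falls below min_mass are frozen at
// their previous mean for that iteration (the M-step update is 0/0 there).

// [[Rcpp::export]]
List em_fit_cpp(const arma::mat& omega, const arma::vec& y,
                arma::vec u, double s2, double tol, int max_iter,
                const arma::vec& cvec, bool constrained, double min_mass,
                bool keep_posteriors) {
  const int n = omega.n_rows, G = omega.n_cols;
  arma::mat P(n, G);
  arma::vec y2 = arma::square(y);
  std::vector<double> trace;
  trace.reserve(64);
  double ll = -std::numeric_limits<double>::infinity();
  double ll_prev = -std::numeric_limits<double>::infinity();
  bool converged = false;
  int it;

  for (it = 1; it <= max_iter; ++it) {
    // ---- E step (log space, per-row max subtraction over omega > 0) ----
    const double c0 = -0.5 * std::log(2.0 * M_PI * s2);
    const double inv2s2 = 0.5 / s2;
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double a = -std::numeric_limits<double>::infinity();
      for (int g = 0; g < G; ++g) {
        if (omega(i, g) > 0.0) {
          const double d = y[i] - u[g];
          const double ld = c0 - d * d * inv2s2;
          P(i, g) = ld;
          if (ld > a) a = ld;
        }
      }
      if (!std::isfinite(a))
        stop("offspring %d has an all-zero mixture-weight row", i + 1);
      double rs = 0.0;
      for (int g = 0; g < G; ++g) {
        const double w =
            omega(i, g) > 0.0 ? omega(i, g) * std::exp(P(i, g) - a) : 0.0;
        P(i, g) = w;
        rs += w;
      }
      const double inv = 1.0 / rs;
      for (int g = 0; g < G; ++g) P(i, g) *= inv;
      ll += std::log(rs) + a;
    }
    trace.push_back(ll);
    if (std::abs(ll - ll_prev) < tol) {
      converged = true;
      break;
    }
    ll_prev = ll;

    // ---- M step ----
    arma::rowvec ng = arma::sum(P, 0);
    arma::vec sy = P.t() * y;
    arma::vec sy2 = P.t() * y2;
    arma::vec ybar(G);
    for (int g = 0; g < G; ++g)
      ybar[g] = ng[g] > min_mass ? sy[g] / ng[g] : u[g];
    if (constrained) {
      double num = 0.0, den = 0.0, off = 0.0;
      for (int g = 0; g < G; ++g) {
        if (ng[g] > min_mass) {
          num += cvec[g] * ybar[g];
          den += cvec[g] * cvec[g] / ng[g];
        } else {
          off += cvec[g] * u[g];  // frozen classes fix part of the constraint
        }
      }
      const double lambda = den > 0.0 ? (num + off) / den : 0.0;
      for (int g = 0; g < G; ++g)
        if (ng[g] > min_mass) u[g] = ybar[g] - lambda * cvec[g] / ng[g];
    } else {
      for (int g = 0; g < G; ++g)
        if (ng[g] > min_mass) u[g] = ybar[g];
    }
    double ss = 0.0;
    for (int g = 0; g < G; ++g)
      ss += sy2[g] - 2.0 * u[g] * sy[g] + u[g] * u[g] * ng[g];
    const double s2_new = ss / n;
    if (!(s2_new > 0.0) || !std::isfinite(s2_new)) {
      // residual variance collapsed (e.g. noise-free data): keep the last
      // positive value, the fit cannot improve further
      converged = true;
      break;
    }
    s2 = s2_new;
  }
  if (it > max_iter) it = max_iter;

  List out = List::create(
      Named("u") = u, Named("sigma2") = s2, Named("loglik") = ll,
      Named("n_iter") = it, Named("converged") = converged,
      Named("loglik_trace") = trace);
  if (keep_posteriors) out["posteriors"] = P;
  return out;
}
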