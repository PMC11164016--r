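#include <Rcpp.h>
using namespace Rcpp;

// Zero-sum constrained logistic lasso over a descending lambda path with
// warm starts. Objective per lambda:
//   (1/n) sum_i [softplus(eta_i) - y_i * eta_i] + lambda * ||beta||_1
//   subject to sum_j beta_j = 0 over the penalized features,
// with eta = b0 + X beta + C theta (C = unpenalized, unconstrained
// covariates).
//
// Augmented Lagrangian outer loop: minimize loss + lambda*L1 + mu*s +
// (rho/2)*s^2 (s = sum of penalized coefficients) by IRLS with cyclic
// coordinate descent / soft thresholding on each working quadratic, then
// update the multiplier (mu += rho*s) and escalate rho (x10, starting at
// rho0, at most max_outer rounds) until |s| <= constraint_tol. The
// multiplier is warm-started along the lambda path, so later lambdas
// typically need a single round. Coordinate sweeps use an active-set
// strategy (full sweep, nonzero-only sweeps, confirming full sweep). The
// path stops refining when the training deviance falls below
// dev_floor_frac of the null deviance (saturated region); remaining
// lambdas reuse the last solution.

static inline double softplus(double x) {
  if (x > 30.0) return x;
  if (x < -30.0) return 0.0;
  return std::log1p(std::exp(x));
}

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// [[Rcpp::export]]
List zs_lasso_path_cpp(NumericMatrix X, NumericVector y, NumericMatrix C,
                       NumericVector lambdas, double tol = 1e-6,
                       int max_irls = 15, int max_outer = 8,
                       double constraint_tol = 1e-6, double rho0 = -1.0,
                       double dev_floor_frac = 0.02) {
  const int n = X.nrow(), p = X.ncol(), q = C.ncol(), L = lambdas.size();
  // default penalty start 1/p: keeps the rank-one constraint coupling of
  // the working quadratic well conditioned for coordinate descent
  if (rho0 <= 0.0) rho0 = 1.0 / p;
  NumericMatrix beta_path(p, L), theta_path(std::max(q, 1), L);
  NumericVector b0_path(L), dev_path(L), resid_path(L);
  IntegerVector n_irls_path(L), n_sweeps_path(L);
  LogicalVector conv_path(L);

  std::vector<double> beta(p, 0.0), theta(q, 0.0), eta(n, 0.0);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double b0 = std::log(ybar / (1.0 - ybar));
  for (int i = 0; i < n; ++i) eta[i] = b0;

  double dev_null = 0.0;
  for (int i = 0; i < n; ++i) dev_null += 2.0 * (softplus(b0) - y[i] * b0);

  std::vector<double> w(n), u(n), z(n), a(p), cden(std::max(q, 1));
  double mu = 0.0;            // constraint multiplier, warm across the path
  bool saturated = false;
  int last_done = -1;

  for (int l = 0; l < L; ++l) {
    if (saturated) {
      for (int j = 0; j < p; ++j) beta_path(j, l) = beta_path(j, last_done);
      for (int m = 0; m < q; ++m) theta_path(m, l) = theta_path(m, last_done);
      b0_path[l] = b0_path[last_done];
      dev_path[l] = dev_path[last_done];
      resid_path[l] = resid_path[last_done];
      conv_path[l] = conv_path[last_done];
      continue;
    }
    const double lambda = lambdas[l];
    int n_irls = 0;
    long n_sweeps = 0;
    double s = 0.0;
    for (int j = 0; j < p; ++j) s += beta[j];
    bool irls_ok = false;
    double rho = rho0;

    for (int outer = 0; outer < max_outer; ++outer) {
      // IRLS to convergence at fixed (mu, rho)
      irls_ok = false;
      for (int irls = 0; irls < max_irls; ++irls) {
        ++n_irls;
        for (int i = 0; i < n; ++i) {
          double pi = 1.0 / (1.0 + std::exp(-eta[i]));
          if (pi < 1e-5) pi = 1e-5;
          if (pi > 1.0 - 1e-5) pi = 1.0 - 1e-5;
          w[i] = pi * (1.0 - pi);
          z[i] = eta[i] + (y[i] - pi) / w[i];
          u[i] = z[i] - eta[i];
        }
        for (int j = 0; j < p; ++j) {
          const double* xj = &X(0, j);
          double aj = 0.0;
          for (int i = 0; i < n; ++i) aj += w[i] * xj[i] * xj[i];
          a[j] = aj / n;
        }
        for (int m = 0; m < q; ++m) {
          double den = 0.0;
          for (int i = 0; i < n; ++i) den += w[i] * C(i, m) * C(i, m);
          cden[m] = den;
        }
        // coordinate descent on the working quadratic
        bool full_pass = true;
        for (int sweep = 0; sweep < 300; ++sweep) {
          ++n_sweeps;
          double max_step = 0.0, scale = 1.0;
          double sw = 0.0, swu = 0.0;
          for (int i = 0; i < n; ++i) { sw += w[i]; swu += w[i] * u[i]; }
          double d0 = swu / sw;
          if (std::fabs(d0) > max_step) max_step = std::fabs(d0);
          b0 += d0;
          for (int i = 0; i < n; ++i) u[i] -= d0;
          for (int m = 0; m < q; ++m) {
            if (cden[m] <= 0) continue;
            double num = 0.0;
            for (int i = 0; i < n; ++i) num += w[i] * u[i] * C(i, m);
            double dm = num / cden[m];
            if (std::fabs(dm) > max_step) max_step = std::fabs(dm);
            theta[m] += dm;
            for (int i = 0; i < n; ++i) u[i] -= dm * C(i, m);
          }
          for (int j = 0; j < p; ++j) {
            if (!full_pass && beta[j] == 0.0) continue;
            const double* xj = &X(0, j);
            double g = 0.0;
            for (int i = 0; i < n; ++i) g += w[i] * u[i] * xj[i];
            g /= n;
            double old = beta[j];
            double cand = soft(g + a[j] * old - mu - rho * (s - old), lambda) /
                          (a[j] + rho);
            double dj = cand - old;
            if (dj != 0.0) {
              if (std::fabs(dj) > max_step) max_step = std::fabs(dj);
              beta[j] = cand;
              s += dj;
              for (int i = 0; i < n; ++i) u[i] -= dj * xj[i];
            }
            if (std::fabs(beta[j]) > scale) scale = std::fabs(beta[j]);
          }
          if (max_step < tol * scale) {
            if (full_pass) break;   // converged on all coordinates
            full_pass = true;       // active set stable; confirming pass
          } else {
            full_pass = false;      // iterate the active set only
          }
        }
        double eta_change = 0.0, scale = 1.0;
        for (int j = 0; j < p; ++j)
          if (std::fabs(beta[j]) > scale) scale = std::fabs(beta[j]);
        for (int i = 0; i < n; ++i) {
          double e = z[i] - u[i];
          double d = std::fabs(e - eta[i]);
          if (d > eta_change) eta_change = d;
          eta[i] = e;
        }
        if (eta_change < 1e-6 * (1.0 + scale)) { irls_ok = true; break; }
      }
      if (std::fabs(s) <= constraint_tol) break;
      mu += rho * s;
      rho *= 10.0;
    }

    double dev = 0.0;
    for (int i = 0; i < n; ++i) dev += 2.0 * (softplus(eta[i]) - y[i] * eta[i]);
    for (int j = 0; j < p; ++j) beta_path(j, l) = beta[j];
    for (int m = 0; m < q; ++m) theta_path(m, l) = theta[m];
    b0_path[l] = b0;
    dev_path[l] = dev;
    resid_path[l] = std::fabs(s);
    conv_path[l] = std::fabs(s) <= constraint_tol && irls_ok;
    n_irls_path[l] = n_irls;
    n_sweeps_path[l] = (int)n_sweeps;
    last_done = l;
    if (dev < dev_floor_frac * dev_null) saturated = true;
  }

  return List::create(_["beta"] = beta_path, _["intercept"] = b0_path,
                      _["theta"] = theta_path, _["deviance"] = dev_path,
                      _["constraint_residual"] = resid_path,
                      _["converged"] = conv_path,
                      _["n_irls"] = n_irls_path,
                      _["n_sweeps"] = n_sweeps_path);
}
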