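#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Weighted-L1 penalized logistic regression by cyclic coordinate descent.
//
// Objective (per lambda):
//   f(b0, beta) = (1/n) * sum_i [ log(1 + exp(eta_i)) - y_i * eta_i ]
//                 + lambda * sum_j gamma_j * |beta_j|
// with eta_i = b0 + x_i . beta.  The intercept is never penalized and
// features with gamma_j = 0 are unpenalized.
//
// Outer loop: quadratic (IRLS) approximation of the logistic loss at the
// current iterate; inner loop: coordinate descent with soft-thresholding
// on the penalized weighted least-squares subproblem, restricted to a
// candidate set assembled from the sequential strong rule, the current
// support and the unpenalized features; candidate sets are certified by a
// full KKT pass before a lambda value is accepted.  A step-halving
// safeguard keeps the recorded objective trace non-increasing (the IRLS
// quadratic is not a global majorizer).

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

static double penalized_obj(const NumericVector& y, const NumericVector& eta,
                            const NumericVector& beta,
                            const NumericVector& gamma, double lambda) {
  const int n = y.size(), p = beta.size();
  double loss = 0.0;
  for (int i = 0; i < n; ++i) {
    double e = eta[i];
    double l = (e > 0.0) ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
    loss += l - y[i] * e;
  }
  loss /= n;
  double pen = 0.0;
  for (int j = 0; j < p; ++j) pen += gamma[j] * std::fabs(beta[j]);
  return loss + lambda * pen;
}

// (1/n) X^T (mu - y), full length-p gradient of the mean logistic loss
static void full_gradient(const NumericMatrix& X, const NumericVector& y,
                          const NumericVector& eta, NumericVector& grad) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> res(n);
  for (int i = 0; i < n; ++i)
    res[i] = 1.0 / (1.0 + std::exp(-eta[i])) - y[i];
  for (int j = 0; j < p; ++j) {
    const double* xj = &X(0, j);
    double g = 0.0;
    for (int i = 0; i < n; ++i) g += xj[i] * res[i];
    grad[j] = g / n;
  }
}

static void update_eta(const NumericMatrix& X, const NumericVector& beta,
                       double b0, NumericVector& eta) {
  const int n = X.nrow(), p = X.ncol();
  for (int i = 0; i < n; ++i) eta[i] = b0;
  for (int j = 0; j < p; ++j) {
    if (beta[j] == 0.0) continue;
    const double* xj = &X(0, j);
    const double bj = beta[j];
    for (int i = 0; i < n; ++i) eta[i] += xj[i] * bj;
  }
}

// [[Rcpp::export(name = ".cd_path")]]
List cd_path(NumericMatrix X, NumericVector y, NumericVector gamma,
             NumericVector lambdas, double tol, int max_sweeps,
             int max_outer, bool trace_objective,
             NumericVector beta_init, double b0_init) {
  const int n = X.nrow(), p = X.ncol(), nlam = lambdas.size();
  const double PMIN = 1e-5;
  const int MAX_SWEEPS_PER_QUAD = 1000;
  const double obj_tol = tol * 1e-2;   // outer stop on objective stall

  NumericVector beta = clone(beta_init);   // warm-started across lambdas
  double b0 = b0_init;

  NumericMatrix beta_out(p, nlam);
  NumericVector b0_out(nlam), kkt_out(nlam);
  IntegerVector sweeps_out(nlam);
  LogicalVector conv_out(nlam);
  List traces(nlam);

  NumericVector eta(n), w(n), r(n), grad(p), xwx(p);
  std::vector<bool> cand(p);

  update_eta(X, beta, b0, eta);
  full_gradient(X, y, eta, grad);      // used by the strong rule at l = 0
  double lam_prev = lambdas[0];

  for (int l = 0; l < nlam; ++l) {
    const double lam = lambdas[l];
    int sweeps = 0;
    bool converged = false;
    std::vector<double> trace;

    // sequential strong rule + current support + unpenalized features
    const double thr = 2.0 * lam - lam_prev;
    for (int j = 0; j < p; ++j) {
      cand[j] = (gamma[j] == 0.0) || (beta[j] != 0.0) ||
                (std::fabs(grad[j]) >= gamma[j] * thr);
    }

    double obj = penalized_obj(y, eta, beta, gamma, lam);
    if (trace_objective) trace.push_back(obj);

    bool certified = false;
    while (!certified) {
      // ---- solve on the candidate set ----
      for (int outer = 0; outer < max_outer && sweeps < max_sweeps; ++outer) {
        for (int i = 0; i < n; ++i) {
          double mu = 1.0 / (1.0 + std::exp(-eta[i]));
          double mui = std::min(std::max(mu, PMIN), 1.0 - PMIN);
          w[i] = mui * (1.0 - mui);
          r[i] = (y[i] - mu) / w[i];     // residual of the working response
        }
        double wsum = 0.0;
        for (int i = 0; i < n; ++i) wsum += w[i];
        for (int j = 0; j < p; ++j) {
          if (!cand[j]) continue;
          const double* xj = &X(0, j);
          double s = 0.0;
          for (int i = 0; i < n; ++i) s += w[i] * xj[i] * xj[i];
          xwx[j] = s / n;
        }

        NumericVector beta_prev = clone(beta);
        const double b0_prev = b0;

        // one coordinate update; returns the weighted squared change
        // xwx_j * delta^2 (glmnet's convergence measure)
        auto upd_coord = [&](int j) -> double {
          if (xwx[j] <= 0.0) return 0.0;
          const double* xj = &X(0, j);
          double num = 0.0;
          for (int i = 0; i < n; ++i) num += w[i] * xj[i] * r[i];
          num = num / n + xwx[j] * beta[j];
          double bj = soft(num, lam * gamma[j]) / xwx[j];
          double d = bj - beta[j];
          if (d != 0.0) {
            for (int i = 0; i < n; ++i) r[i] -= d * xj[i];
            beta[j] = bj;
          }
          return d * d * xwx[j];
        };
        auto upd_intercept = [&]() -> double {
          double num = 0.0;
          for (int i = 0; i < n; ++i) num += w[i] * r[i];
          double d = num / wsum;
          if (d != 0.0) {
            for (int i = 0; i < n; ++i) r[i] -= d;
            b0 += d;
          }
          return d * d * (wsum / n);
        };

        // full candidate sweep, then cheap sweeps over the nonzero
        // support until stable, repeated until the full sweep is stable
        int quad_sweeps = 0;
        double maxdel;
        do {
          maxdel = upd_intercept();
          for (int j = 0; j < p; ++j) {
            if (!cand[j]) continue;
            maxdel = std::max(maxdel, upd_coord(j));
          }
          ++sweeps; ++quad_sweeps;
          if (maxdel < tol) break;
          std::vector<int> act;
          act.reserve(64);
          for (int j = 0; j < p; ++j)
            if (cand[j] && (beta[j] != 0.0 || gamma[j] == 0.0)) act.push_back(j);
          double adel;
          do {
            adel = upd_intercept();
            for (size_t a = 0; a < act.size(); ++a)
              adel = std::max(adel, upd_coord(act[a]));
            ++sweeps; ++quad_sweeps;
          } while (adel >= tol && quad_sweeps < MAX_SWEEPS_PER_QUAD &&
                   sweeps < max_sweeps);
        } while (quad_sweeps < MAX_SWEEPS_PER_QUAD && sweeps < max_sweeps);

        // IRLS step with halving until the true objective is non-increasing
        NumericVector beta_new = clone(beta);
        const double b0_new = b0;
        double step = 1.0, obj_new = 0.0;
        for (int h = 0; h < 40; ++h) {
          if (h > 0) {
            step *= 0.5;
            for (int j = 0; j < p; ++j)
              beta[j] = beta_prev[j] + step * (beta_new[j] - beta_prev[j]);
            b0 = b0_prev + step * (b0_new - b0_prev);
          }
          update_eta(X, beta, b0, eta);
          obj_new = penalized_obj(y, eta, beta, gamma, lam);
          if (obj_new <= obj + 1e-12) break;
        }
        if (obj_new > obj + 1e-12) {    // no acceptable step: restore
          beta = clone(beta_prev);
          b0 = b0_prev;
          update_eta(X, beta, b0, eta);
          obj_new = obj;
        }
        if (trace_objective) trace.push_back(obj_new);

        double db0 = b0 - b0_prev;
        double maxchg = db0 * db0 * (wsum / n);
        for (int j = 0; j < p; ++j) {
          double d = beta[j] - beta_prev[j];
          maxchg = std::max(maxchg, d * d * xwx[j]);
        }
        const double objchg = obj - obj_new;
        obj = obj_new;
        if (maxchg < tol || objchg < obj_tol) { converged = true; break; }
      }

      // ---- certify with a full KKT pass; admit violators ----
      const double kkt_eps = 0.1 * std::sqrt(tol);
      full_gradient(X, y, eta, grad);
      certified = true;
      for (int j = 0; j < p; ++j) {
        if (cand[j]) continue;
        if (std::fabs(grad[j]) > lam * gamma[j] + kkt_eps) {
          cand[j] = true;
          certified = false;
        }
      }
      if (!certified) converged = false;
      if (sweeps >= max_sweeps) break;
    }

    double kkt = 0.0;
    for (int j = 0; j < p; ++j) {
      double v;
      if (beta[j] != 0.0) {
        v = std::fabs(grad[j] + lam * gamma[j] * ((beta[j] > 0) ? 1.0 : -1.0));
      } else {
        v = std::max(0.0, std::fabs(grad[j]) - lam * gamma[j]);
      }
      kkt = std::max(kkt, v);
    }

    beta_out(_, l) = beta;
    b0_out[l] = b0;
    kkt_out[l] = kkt;
    sweeps_out[l] = sweeps;
    conv_out[l] = converged;
    traces[l] = wrap(trace);
    lam_prev = lam;
  }

  return List::create(_["beta"] = beta_out, _["intercept"] = b0_out,
                      _["kkt"] = kkt_out, _["sweeps"] = sweeps_out,
                      _["converged"] = conv_out, _["objective"] = traces);
}
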