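#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double plogis_(double eta) {
  if (eta > 0) return 1.0 / (1.0 + std::exp(-eta));
  double e = std::exp(eta);
  return e / (1.0 + e);
}

static inline double log1pexp_(double eta) {
  // numerically stable log(1 + exp(eta))
  if (eta > 35.0) return eta;
  if (eta < -35.0) return std::exp(eta);
  return std::log1p(std::exp(eta));
}

// Single-site Gibbs sampler for a {0,1} Ising model with conditionals
// P(x_i = 1 | x_-i) = logistic(tau_i + sum_j W_ij x_j).
// One "sweep" updates all p sites in order; draws are recorded every `thin`
// sweeps after `burn_in` sweeps.  Uses R's RNG so set.seed() governs.
// [[Rcpp::export]]
IntegerMatrix gibbs_sample_cpp(NumericMatrix W, NumericVector tau,
                               int n, int burn_in, int thin) {
  int p = W.ncol();
  IntegerMatrix out(n, p);
  std::vector<int> x(p);
  for (int j = 0; j < p; ++j)
    x[j] = (unif_rand() < plogis_(tau[j])) ? 1 : 0;
  int total = burn_in + n * thin;
  int row = 0;
  for (int s = 0; s < total; ++s) {
    for (int j = 0; j < p; ++j) {
      double eta = tau[j];
      for (int k = 0; k < p; ++k)
        if (x[k]) eta += W(k, j);
      double pr = plogis_(eta);
      x[j] = (unif_rand() < pr) ? 1 : 0;
    }
    if (s >= burn_in && ((s - burn_in) % thin == thin - 1)) {
      for (int j = 0; j < p; ++j) out(row, j) = x[j];
      ++row;
    }
  }
  return out;
}

// L1-penalised logistic regression path by IRLS + cyclic coordinate descent
// (intercept unpenalised, warm starts down a decreasing lambda grid).
// Objective: -(1/n) loglik + lambda * sum_j |b_j|.
// Exploits binary predictors: inner products over column j reduce to sums
// over the observations with x_ij = 1, and an active-set strategy sweeps
// only current non-zeros between full passes.
// Returns per-lambda coefficients, intercept, summed log-likelihood,
// non-zero count, and the smooth-part gradient (for KKT checks).
// [[Rcpp::export]]
List logistic_lasso_path_cpp(NumericMatrix X, IntegerVector y,
                             NumericVector lambdas,
                             double tol, int max_outer, int max_inner) {
  int n = X.nrow(), d = X.ncol(), L = lambdas.size();
  NumericMatrix beta_out(d, L), grad_out(d, L);
  NumericVector b0_out(L), ll_out(L);
  IntegerVector k_out(L);

  // support lists: rows where x_ij = 1 (requires 0/1 coding, checked in R)
  std::vector< std::vector<int> > supp(d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < n; ++i)
      if (X(i, j) != 0.0) supp[j].push_back(i);

  std::vector<double> b(d, 0.0), eta(n, 0.0);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  if (ybar <= 0.0 || ybar >= 1.0)
    stop("response column is constant");
  double b0 = std::log(ybar / (1.0 - ybar));
  for (int i = 0; i < n; ++i) eta[i] = b0;

  const double bcap = 15.0, wfloor = 1e-5;
  std::vector<double> w(n), r(n), xsq(d);

  // one coordinate update; returns |change|
  auto update_coord = [&](int j, double lam) -> double {
    if (xsq[j] <= 0.0) return 0.0;
    double num = 0.0;
    const std::vector<int>& s = supp[j];
    for (size_t t = 0; t < s.size(); ++t) num += w[s[t]] * r[s[t]];
    num = num / n + xsq[j] * b[j];
    double bnew;
    if (num > lam) bnew = (num - lam) / xsq[j];
    else if (num < -lam) bnew = (num + lam) / xsq[j];
    else bnew = 0.0;
    if (bnew > bcap) bnew = bcap;
    if (bnew < -bcap) bnew = -bcap;
    double dj = bnew - b[j];
    if (dj != 0.0) {
      b[j] = bnew;
      for (size_t t = 0; t < s.size(); ++t) r[s[t]] -= dj;
    }
    return std::fabs(dj);
  };
  double wsum = 0.0;
  auto update_intercept = [&]() -> double {
    double num0 = 0.0;
    for (int i = 0; i < n; ++i) num0 += w[i] * r[i];
    double d0 = num0 / wsum;
    if (d0 != 0.0) {
      b0 += d0;
      for (int i = 0; i < n; ++i) r[i] -= d0;
    }
    return std::fabs(d0);
  };

  std::vector<double> prob(n), grad(d);
  std::vector<char> cand(d, 0);
  // gradient of the smooth part at the current eta, all coordinates
  auto full_gradient = [&]() {
    for (int i = 0; i < n; ++i) prob[i] = plogis_(eta[i]);
    for (int j = 0; j < d; ++j) {
      double g = 0.0;
      const std::vector<int>& s = supp[j];
      for (size_t t = 0; t < s.size(); ++t) g -= y[s[t]] - prob[s[t]];
      grad[j] = g / n;
    }
  };
  full_gradient();

  for (int l = 0; l < L; ++l) {
    double lam = lambdas[l];
    // sequential strong rule on the gradient at the previous solution
    double lam_prev = (l == 0) ? lambdas[0] : lambdas[l - 1];
    for (int j = 0; j < d; ++j)
      cand[j] = (b[j] != 0.0) || (std::fabs(grad[j]) >= 2.0 * lam - lam_prev);
    for (int round = 0; round < 10; ++round) {
      for (int outer = 0; outer < max_outer; ++outer) {
        // IRLS expansion at current (b0, b); r holds working residuals
        for (int i = 0; i < n; ++i) {
          double p_i = plogis_(eta[i]);
          double w_i = p_i * (1.0 - p_i);
          if (w_i < wfloor) w_i = wfloor;
          w[i] = w_i;
          r[i] = (y[i] - p_i) / w_i;
        }
        wsum = 0.0;
        for (int i = 0; i < n; ++i) wsum += w[i];
        for (int j = 0; j < d; ++j) {
          if (!cand[j]) continue;
          double s = 0.0;
          const std::vector<int>& sj = supp[j];
          for (size_t t = 0; t < sj.size(); ++t) s += w[sj[t]];
          xsq[j] = s / n;
        }
        // penalised weighted least squares on the candidate set: full
        // candidate sweeps to fix the active set, then cheap sweeps over
        // the current non-zeros
        double delta_outer = -1.0;
        for (int pass = 0; pass < max_inner; ++pass) {
          double maxdelta = update_intercept();
          for (int j = 0; j < d; ++j) {
            if (!cand[j]) continue;
            double dj = update_coord(j, lam);
            if (dj > maxdelta) maxdelta = dj;
          }
          if (delta_outer < 0) delta_outer = maxdelta;
          if (maxdelta < tol) break;
          for (int pass2 = 0; pass2 < max_inner; ++pass2) {
            double md = update_intercept();
            for (int j = 0; j < d; ++j) {
              if (b[j] == 0.0 || !cand[j]) continue;
              double dj = update_coord(j, lam);
              if (dj > md) md = dj;
            }
            if (md < tol) break;
          }
        }
        // rebuild the linear predictor from the coefficients
        for (int i = 0; i < n; ++i) eta[i] = b0;
        for (int j = 0; j < d; ++j) {
          if (b[j] == 0.0) continue;
          const std::vector<int>& s = supp[j];
          for (size_t t = 0; t < s.size(); ++t) eta[s[t]] += b[j];
        }
        if (delta_outer < tol) break;
      }
      // KKT check over the excluded coordinates; admit violators
      full_gradient();
      bool violation = false;
      for (int j = 0; j < d; ++j) {
        if (!cand[j] && std::fabs(grad[j]) > lam) {
          cand[j] = 1;
          violation = true;
        }
      }
      if (!violation) break;
    }
    // record
    double ll = 0.0;
    for (int i = 0; i < n; ++i)
      ll += y[i] * eta[i] - log1pexp_(eta[i]);
    int k = 0;
    for (int j = 0; j < d; ++j) {
      beta_out(j, l) = b[j];
      if (b[j] != 0.0) ++k;
    }
    // gradient of the (unpenalised) smooth part at the solution
    // (grad is fresh: full_gradient() ran after the last KKT round)
    for (int j = 0; j < d; ++j) grad_out(j, l) = grad[j];
    b0_out[l] = b0;
    ll_out[l] = ll;
    k_out[l] = k;
  }
  return List::create(_["beta"] = beta_out, _["intercept"] = b0_out,
                      _["loglik"] = ll_out, _["df"] = k_out,
                      _["grad"] = grad_out);
}
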