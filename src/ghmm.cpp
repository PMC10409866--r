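#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian-emission HMM machinery used by the trace idealizer.
// Scaled forward-backward (Baum-Welch) and Viterbi decoding; emission
// densities are floored to keep the scaling well-defined for extreme
// outliers at small fitted widths.

static inline double dnorm_floor(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  double d = std::exp(-0.5 * z * z) / (sd * 2.5066282746310002);
  return d < 1e-300 ? 1e-300 : d;
}

// [[Rcpp::export]]
List ghmm_em_cpp(NumericVector x, NumericVector mu0, NumericVector sigma0,
                 int max_iter, double tol, double sigma_floor,
                 double sigma_ceiling) {
  int n = x.size(), K = mu0.size();
  NumericVector mu = clone(mu0), sigma = clone(sigma0);
  NumericVector init(K, 1.0 / K);
  NumericMatrix trans(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j)
      trans(i, j) = (i == j) ? 0.9 : 0.1 / std::max(1, K - 1);
  if (K == 1) trans(0, 0) = 1.0;

  NumericMatrix B(n, K), alpha(n, K), beta(n, K), gamma(n, K);
  NumericVector scale(n);
  double loglik = R_NegInf;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    for (int t = 0; t < n; ++t)
      for (int k = 0; k < K; ++k)
        B(t, k) = dnorm_floor(x[t], mu[k], sigma[k]);

    // forward
    double s = 0;
    for (int k = 0; k < K; ++k) { alpha(0, k) = init[k] * B(0, k); s += alpha(0, k); }
    scale[0] = s;
    for (int k = 0; k < K; ++k) alpha(0, k) /= s;
    for (int t = 1; t < n; ++t) {
      s = 0;
      for (int k = 0; k < K; ++k) {
        double a = 0;
        for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * trans(j, k);
        alpha(t, k) = a * B(t, k);
        s += alpha(t, k);
      }
      scale[t] = s;
      for (int k = 0; k < K; ++k) alpha(t, k) /= s;
    }
    double ll = 0;
    for (int t = 0; t < n; ++t) ll += std::log(scale[t]);

    // backward
    for (int k = 0; k < K; ++k) beta(n - 1, k) = 1.0;
    for (int t = n - 2; t >= 0; --t)
      for (int k = 0; k < K; ++k) {
        double b = 0;
        for (int j = 0; j < K; ++j) b += trans(k, j) * B(t + 1, j) * beta(t + 1, j);
        beta(t, k) = b / scale[t + 1];
      }

    // posteriors
    for (int t = 0; t < n; ++t) {
      double g = 0;
      for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
      for (int k = 0; k < K; ++k) gamma(t, k) /= g;
    }

    // M-step
    for (int k = 0; k < K; ++k) init[k] = gamma(0, k);
    if (K > 1) {
      std::vector<double> num(K * K, 0.0), denom(K, 0.0), xi(K);
      for (int t = 0; t < n - 1; ++t)
        for (int j = 0; j < K; ++j) {
          double row = 0, aj = alpha(t, j);
          for (int k = 0; k < K; ++k) {
            xi[k] = aj * trans(j, k) * B(t + 1, k) * beta(t + 1, k);
            row += xi[k];
          }
          if (row > 0) {
            // alpha/beta are scaled, so xi/row * gamma(t,j) is exact
            double g = gamma(t, j) / row;
            for (int k = 0; k < K; ++k) num[j * K + k] += g * xi[k];
            denom[j] += gamma(t, j);
          }
        }
      for (int j = 0; j < K; ++j)
        if (denom[j] > 0)
          for (int k = 0; k < K; ++k) trans(j, k) = num[j * K + k] / denom[j];
    }
    for (int k = 0; k < K; ++k) {
      double w = 0, m = 0;
      for (int t = 0; t < n; ++t) { w += gamma(t, k); m += gamma(t, k) * x[t]; }
      if (w > 1e-10) {
        m /= w;
        double v = 0;
        for (int t = 0; t < n; ++t) {
          double d = x[t] - m;
          v += gamma(t, k) * d * d;
        }
        mu[k] = m;
        // FRET states are narrow; the ceiling stops a single wide
        // component from acting as an outlier catch-all
        sigma[k] = std::min(std::max(std::sqrt(v / w), sigma_floor),
                            sigma_ceiling);
      }
    }

    if (iter > 0 && std::fabs(ll - loglik) < tol * std::fabs(ll) + tol) {
      loglik = ll;
      break;
    }
    loglik = ll;
  }

  return List::create(_["loglik"] = loglik, _["mu"] = mu,
                      _["sigma"] = sigma, _["trans"] = trans,
                      _["init"] = init, _["iterations"] = iter + 1);
}

// [[Rcpp::export]]
IntegerVector ghmm_viterbi_cpp(NumericVector x, NumericVector mu,
                               NumericVector sigma, NumericMatrix trans,
                               NumericVector init) {
  int n = x.size(), K = mu.size();
  NumericMatrix delta(n, K);
  IntegerMatrix psi(n, K);
  for (int k = 0; k < K; ++k)
    delta(0, k) = std::log(init[k] + 1e-300) +
                  std::log(dnorm_floor(x[0], mu[k], sigma[k]));
  for (int t = 1; t < n; ++t)
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) + std::log(trans(j, k) + 1e-300);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + std::log(dnorm_floor(x[t], mu[k], sigma[k]));
      psi(t, k) = arg;
    }
  IntegerVector path(n);
  double best = R_NegInf;
  for (int k = 0; k < K; ++k)
    if (delta(n - 1, k) > best) { best = delta(n - 1, k); path[n - 1] = k; }
  for (int t = n - 2; t >= 0; --t)
    path[t] = psi(t + 1, path[t + 1]);
  return path + 1;   // 1-based state indices
}
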