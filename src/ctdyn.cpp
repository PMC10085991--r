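#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for a Gaussian-emission HMM on one trace.
// Returns log-likelihood, per-frame posteriors gamma (n x k) and the summed
// transition posteriors xi (k x k), the sufficient statistics for one
// Baum-Welch iteration.
// [[Rcpp::export]]
List hmm_forward_backward(NumericVector obs, NumericVector means,
                          NumericVector sds, NumericMatrix trans,
                          NumericVector init) {
  const int n = obs.size(), k = means.size();
  NumericMatrix b(n, k);        // emission densities
  for (int t = 0; t < n; ++t)
    for (int j = 0; j < k; ++j)
      b(t, j) = R::dnorm(obs[t], means[j], sds[j], 0) + 1e-300;

  NumericMatrix alpha(n, k), beta(n, k);
  NumericVector scale(n);
  double ll = 0.0;

  for (int j = 0; j < k; ++j) alpha(0, j) = init[j] * b(0, j);
  double s = 0.0;
  for (int j = 0; j < k; ++j) s += alpha(0, j);
  if (s <= 0) s = 1e-300;
  scale[0] = s; ll += std::log(s);
  for (int j = 0; j < k; ++j) alpha(0, j) /= s;

  for (int t = 1; t < n; ++t) {
    s = 0.0;
    for (int j = 0; j < k; ++j) {
      double a = 0.0;
      for (int i = 0; i < k; ++i) a += alpha(t - 1, i) * trans(i, j);
      alpha(t, j) = a * b(t, j);
      s += alpha(t, j);
    }
    if (s <= 0) s = 1e-300;
    scale[t] = s; ll += std::log(s);
    for (int j = 0; j < k; ++j) alpha(t, j) /= s;
  }

  for (int j = 0; j < k; ++j) beta(n - 1, j) = 1.0;
  for (int t = n - 2; t >= 0; --t)
    for (int i = 0; i < k; ++i) {
      double bsum = 0.0;
      for (int j = 0; j < k; ++j)
        bsum += trans(i, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, i) = bsum / scale[t + 1];
    }

  NumericMatrix gamma(n, k);
  for (int t = 0; t < n; ++t) {
    double g = 0.0;
    for (int j = 0; j < k; ++j) { gamma(t, j) = alpha(t, j) * beta(t, j); g += gamma(t, j); }
    if (g > 0) for (int j = 0; j < k; ++j) gamma(t, j) /= g;
  }

  NumericMatrix xi(k, k);
  for (int t = 0; t < n - 1; ++t) {
    double z = 0.0;
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j)
        z += alpha(t, i) * trans(i, j) * b(t + 1, j) * beta(t + 1, j);
    if (z <= 0) continue;
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < k; ++j)
        xi(i, j) += alpha(t, i) * trans(i, j) * b(t + 1, j) * beta(t + 1, j) / z;
  }

  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// Viterbi path (1-based state labels) for a Gaussian-emission HMM.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericVector obs, NumericVector means,
                          NumericVector sds, NumericMatrix trans,
                          NumericVector init) {
  const int n = obs.size(), k = means.size();
  NumericMatrix delta(n, k);
  IntegerMatrix psi(n, k);
  NumericMatrix ltrans(k, k);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j)
      ltrans(i, j) = std::log(trans(i, j) + 1e-300);

  for (int j = 0; j < k; ++j)
    delta(0, j) = std::log(init[j] + 1e-300) + R::dnorm(obs[0], means[j], sds[j], 1);
  for (int t = 1; t < n; ++t)
    for (int j = 0; j < k; ++j) {
      double best = R_NegInf; int arg = 0;
      for (int i = 0; i < k; ++i) {
        double v = delta(t - 1, i) + ltrans(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + R::dnorm(obs[t], means[j], sds[j], 1);
      psi(t, j) = arg;
    }

  IntegerVector path(n);
  double best = R_NegInf; int arg = 0;
  for (int j = 0; j < k; ++j)
    if (delta(n - 1, j) > best) { best = delta(n - 1, j); arg = j; }
  path[n - 1] = arg + 1;
  for (int t = n - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}

// Euler-Maruyama path on a sum-of-Gaussian-wells potential with harmonic
// walls. Uses R's RNG so results follow set.seed(). Returns n_steps + 1
// positions including the start.
// [[Rcpp::export]]
NumericVector langevin_path(double x0, int n_steps, double dt,
                            double mobility, double noise_amp,
                            NumericVector centers, NumericVector depths,
                            double width, NumericVector bounds,
                            double wall_stiffness) {
  NumericVector xs(n_steps + 1);
  xs[0] = x0;
  const double w2 = width * width;
  double x = x0;
  for (int t = 0; t < n_steps; ++t) {
    double f = 0.0;
    for (int j = 0; j < centers.size(); ++j) {
      double dx = x - centers[j];
      f -= depths[j] * dx / w2 * std::exp(-dx * dx / (2.0 * w2));
    }
    if (x < bounds[0]) f -= wall_stiffness * (x - bounds[0]);
    if (x > bounds[1]) f -= wall_stiffness * (x - bounds[1]);
    x += mobility * f * dt;
    if (noise_amp > 0) x += noise_amp * R::norm_rand();
    xs[t + 1] = x;
  }
  return xs;
}
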