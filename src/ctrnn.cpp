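#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// coupling 0 ("source"):  dg_i/dt = (-g_i + sum_j W(i,j) sigmoid(g_j + theta_j) + I_i) / tau_i
// coupling 1 ("summed"):  dg_i/dt = (-g_i + sigmoid(theta_i + sum_j W(i,j) g_j) + I_i) / tau_i
static void deriv(int n, const double* W, const double* tau,
                  const double* theta, const double* g, const double* input,
                  double* out, std::vector<double>& s, int coupling) {
  if (coupling == 0) {
    for (int j = 0; j < n; ++j) s[j] = sigmoid(g[j] + theta[j]);
    for (int i = 0; i < n; ++i) {
      double acc = -g[i];
      const double* wrow = W + i;  // column-major: W[i + n*j]
      for (int j = 0; j < n; ++j) acc += wrow[(size_t)n * j] * s[j];
      if (input) acc += input[i];
      out[i] = acc / tau[i];
    }
  } else {
    for (int i = 0; i < n; ++i) {
      double acc = theta[i];
      const double* wrow = W + i;
      for (int j = 0; j < n; ++j) acc += wrow[(size_t)n * j] * g[j];
      double v = -g[i] + sigmoid(acc);
      if (input) v += input[i];
      out[i] = v / tau[i];
    }
  }
}

// Classic fixed-step RK4 from t=0 over n_steps steps of size `step`.
// I (optional) is the external input sampled on the half-step grid:
// n x (2*n_steps + 1), column 2k = t_k, column 2k+1 = t_k + step/2.
// Returns the full trajectory, n x (n_steps + 1).
// [[Rcpp::export]]
NumericMatrix ctrnn_integrate_cpp(NumericMatrix W, NumericVector tau,
                                  NumericVector theta, NumericVector g0,
                                  int n_steps, double step, NumericMatrix I,
                                  int coupling) {
  const int n = W.nrow();
  if (W.ncol() != n || tau.size() != n || theta.size() != n || g0.size() != n)
    stop("inconsistent CTRNN dimensions");
  for (int i = 0; i < n; ++i)
    if (!(tau[i] > 0)) stop("time constants must be positive");
  const bool has_input = I.ncol() > 0;
  if (has_input && (I.nrow() != n || I.ncol() != 2 * n_steps + 1))
    stop("external input grid has wrong shape");

  NumericMatrix out(n, n_steps + 1);
  std::vector<double> g(g0.begin(), g0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n), s(n);
  const double* Wp = W.begin();
  const double* taup = tau.begin();
  const double* thp = theta.begin();
  for (int i = 0; i < n; ++i) out(i, 0) = g[i];

  for (int k = 0; k < n_steps; ++k) {
    const double* I0 = has_input ? &I(0, 2 * k) : nullptr;
    const double* Ih = has_input ? &I(0, 2 * k + 1) : nullptr;
    const double* I1 = has_input ? &I(0, 2 * k + 2) : nullptr;
    deriv(n, Wp, taup, thp, g.data(), I0, k1.data(), s, coupling);
    for (int i = 0; i < n; ++i) tmp[i] = g[i] + 0.5 * step * k1[i];
    deriv(n, Wp, taup, thp, tmp.data(), Ih, k2.data(), s, coupling);
    for (int i = 0; i < n; ++i) tmp[i] = g[i] + 0.5 * step * k2[i];
    deriv(n, Wp, taup, thp, tmp.data(), Ih, k3.data(), s, coupling);
    for (int i = 0; i < n; ++i) tmp[i] = g[i] + step * k3[i];
    deriv(n, Wp, taup, thp, tmp.data(), I1, k4.data(), s, coupling);
    for (int i = 0; i < n; ++i) {
      g[i] += step / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      out(i, k + 1) = g[i];
    }
  }
  return out;
}

// Fitness of a whole GA population. Chromosome layout (0-based):
// locus n*j + i = W(i,j), then n time constants, then n offsets.
// g0 is fixed to the observed first time point. obs_idx are 0-based grid
// indices of the observation times. Fitness = -MSE - lambda * sum|W|.
// mask (optional, n x n, 0/1): W support restriction; masked entries are
// treated as zero.
// [[Rcpp::export]]
NumericVector ctrnn_fitness_cpp(NumericMatrix pop, NumericMatrix observed,
                                IntegerVector obs_idx, int n_steps,
                                double step, double sparsity_lambda,
                                IntegerMatrix mask, int coupling) {
  const int P = pop.nrow();
  const int n = observed.nrow();
  const int T = observed.ncol();
  const size_t L = (size_t)n * n + 2 * n;
  if ((size_t)pop.ncol() != L) stop("chromosome length mismatch");
  if (obs_idx.size() != T) stop("observation index length mismatch");
  const bool has_mask = mask.ncol() == n && mask.nrow() == n;

  NumericVector fit(P);
  std::vector<double> W((size_t)n * n), tau(n), theta(n), g(n);
  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n), s(n);
  std::vector<int> is_obs(n_steps + 1, -1);
  for (int t = 0; t < T; ++t) {
    if (obs_idx[t] < 0 || obs_idx[t] > n_steps) stop("observation index out of grid");
    is_obs[obs_idx[t]] = t;
  }

  for (int p = 0; p < P; ++p) {
    double wsum = 0.0;
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        double w = pop(p, (size_t)n * j + i);
        if (has_mask && mask(i, j) == 0) w = 0.0;
        W[(size_t)n * j + i] = w;
        wsum += std::fabs(w);
      }
    for (int i = 0; i < n; ++i) {
      tau[i] = pop(p, (size_t)n * n + i);
      theta[i] = pop(p, (size_t)n * n + n + i);
      if (!(tau[i] > 0)) stop("time constants must be positive");
      g[i] = observed(i, 0);
    }
    double sse = 0.0;
    if (is_obs[0] >= 0)
      for (int i = 0; i < n; ++i) {
        double d = g[i] - observed(i, is_obs[0]);
        sse += d * d;
      }
    for (int k = 0; k < n_steps; ++k) {
      deriv(n, W.data(), tau.data(), theta.data(), g.data(), nullptr, k1.data(), s, coupling);
      for (int i = 0; i < n; ++i) tmp[i] = g[i] + 0.5 * step * k1[i];
      deriv(n, W.data(), tau.data(), theta.data(), tmp.data(), nullptr, k2.data(), s, coupling);
      for (int i = 0; i < n; ++i) tmp[i] = g[i] + 0.5 * step * k2[i];
      deriv(n, W.data(), tau.data(), theta.data(), tmp.data(), nullptr, k3.data(), s, coupling);
      for (int i = 0; i < n; ++i) tmp[i] = g[i] + step * k3[i];
      deriv(n, W.data(), tau.data(), theta.data(), tmp.data(), nullptr, k4.data(), s, coupling);
      for (int i = 0; i < n; ++i)
        g[i] += step / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (is_obs[k + 1] >= 0) {
        int t = is_obs[k + 1];
        for (int i = 0; i < n; ++i) {
          double d = g[i] - observed(i, t);
          sse += d * d;
        }
      }
    }
    fit[p] = -sse / ((double)n * T) - sparsity_lambda * wsum;
  }
  return fit;
}
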