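#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Multi-well potential used throughout the synthetic module:
//   U(x) = sum_b -depth_b * exp(-sum_j (x_j - c_bj)^2 / (2 w_bj^2))
//        + 0.5 * sum_j harmonic_k_j * x_j^2
//        + g * (x_escape - gate_ref) * x_gate   (bilinear gate coupling)
//        + k_wall * sum_j max(0, |x_j| - L_j)^2   (confinement)
// Gradients are analytic; the R side validates the spec before calling.

static inline double pot_energy(const double* x, int ndim,
                                const NumericMatrix& centers,
                                const NumericVector& depths,
                                const NumericMatrix& widths,
                                const NumericVector& harmonic_k,
                                double gate_g, int esc_i, int gate_i,
                                double gate_ref,
                                const NumericVector& wall_lo,
                                const NumericVector& wall_hi,
                                double wall_k) {
  double u = 0.0;
  int nb = depths.size();
  for (int b = 0; b < nb; ++b) {
    double s2 = 0.0;
    for (int j = 0; j < ndim; ++j) {
      double d = x[j] - centers(b, j);
      double w = widths(b, j);
      s2 += d * d / (w * w);
    }
    u += -depths[b] * std::exp(-s2 / 2.0);
  }
  for (int j = 0; j < ndim; ++j) {
    u += 0.5 * harmonic_k[j] * x[j] * x[j];
    double lo = wall_lo[j], hi = wall_hi[j];
    if (x[j] < lo) u += wall_k * (lo - x[j]) * (lo - x[j]);
    if (x[j] > hi) u += wall_k * (x[j] - hi) * (x[j] - hi);
  }
  if (gate_g != 0.0 && esc_i >= 0 && gate_i >= 0)
    u += gate_g * (x[esc_i] - gate_ref) * x[gate_i];
  return u;
}

static inline void pot_grad(const double* x, double* g, int ndim,
                            const NumericMatrix& centers,
                            const NumericVector& depths,
                            const NumericMatrix& widths,
                            const NumericVector& harmonic_k,
                            double gate_g, int esc_i, int gate_i,
                            double gate_ref,
                            const NumericVector& wall_lo,
                            const NumericVector& wall_hi,
                            double wall_k) {
  for (int j = 0; j < ndim; ++j) g[j] = 0.0;
  int nb = depths.size();
  for (int b = 0; b < nb; ++b) {
    double s2 = 0.0;
    for (int j = 0; j < ndim; ++j) {
      double d = x[j] - centers(b, j);
      double w = widths(b, j);
      s2 += d * d / (w * w);
    }
    double e = std::exp(-s2 / 2.0);
    // dU/dxj = depth * e * (xj - cj) / w_bj^2
    for (int j = 0; j < ndim; ++j) {
      double w = widths(b, j);
      g[j] += depths[b] * e * (x[j] - centers(b, j)) / (w * w);
    }
  }
  for (int j = 0; j < ndim; ++j) {
    g[j] += harmonic_k[j] * x[j];
    double lo = wall_lo[j], hi = wall_hi[j];
    if (x[j] < lo) g[j] += -2.0 * wall_k * (lo - x[j]);
    if (x[j] > hi) g[j] += 2.0 * wall_k * (x[j] - hi);
  }
  if (gate_g != 0.0 && esc_i >= 0 && gate_i >= 0) {
    g[esc_i] += gate_g * x[gate_i];
    g[gate_i] += gate_g * (x[esc_i] - gate_ref);
  }
}

// [[Rcpp::export]]
double potential_energy_cpp(NumericVector x, NumericMatrix centers,
                            NumericVector depths, NumericMatrix widths,
                            NumericVector harmonic_k, double gate_g,
                            int esc_i, int gate_i, double gate_ref,
                            NumericVector wall_lo,
                            NumericVector wall_hi, double wall_k) {
  return pot_energy(REAL(x), x.size(), centers, depths, widths, harmonic_k,
                    gate_g, esc_i, gate_i, gate_ref, wall_lo, wall_hi, wall_k);
}

// [[Rcpp::export]]
NumericVector potential_gradient_cpp(NumericVector x, NumericMatrix centers,
                                     NumericVector depths, NumericMatrix widths,
                                     NumericVector harmonic_k, double gate_g,
                                     int esc_i, int gate_i, double gate_ref,
                                     NumericVector wall_lo,
                                     NumericVector wall_hi, double wall_k) {
  NumericVector g(x.size());
  pot_grad(REAL(x), REAL(g), x.size(), centers, depths, widths, harmonic_k,
           gate_g, esc_i, gate_i, gate_ref, wall_lo, wall_hi, wall_k);
  return g;
}

// Euler-Maruyama overdamped Langevin with optional moving harmonic bias.
// Uses R's RNG stream (caller sets the seed). Frames saved every save_every
// steps, frame 0 included. Returns list(frames, bias, diverged).
// [[Rcpp::export]]
List langevin_cpp(NumericVector start, int n_steps, double dt, double D,
                  double kT, int save_every, NumericMatrix centers,
                  NumericVector depths, NumericMatrix widths,
                  NumericVector harmonic_k, double gate_g, int esc_i,
                  int gate_i, double gate_ref, NumericVector wall_lo,
                  NumericVector wall_hi, double wall_k, bool bias_on,
                  NumericVector bias_k, NumericVector bias_c0,
                  NumericVector bias_dir, double bias_rate,
                  double domain_limit) {
  RNGScope scope;
  int ndim = start.size();
  int n_save = n_steps / save_every + 1;
  NumericMatrix frames(n_save, ndim);
  NumericMatrix bias(bias_on ? n_save : 1, bias_on ? ndim : 1);
  std::vector<double> x(start.begin(), start.end());
  std::vector<double> g(ndim);
  double mob = D / kT;
  double noise = std::sqrt(2.0 * D * dt);
  bool diverged = false;
  for (int j = 0; j < ndim; ++j) frames(0, j) = x[j];
  if (bias_on)
    for (int j = 0; j < ndim; ++j) bias(0, j) = bias_c0[j];
  int isave = 1;
  for (int t = 1; t <= n_steps; ++t) {
    pot_grad(x.data(), g.data(), ndim, centers, depths, widths, harmonic_k,
             gate_g, esc_i, gate_i, gate_ref, wall_lo, wall_hi, wall_k);
    if (bias_on) {
      // moving harmonic restraint 0.5*k_j*(x_j - c_j(t))^2, c(t) = c0 + v t dir
      double ct = bias_rate * (t - 1) * dt;
      for (int j = 0; j < ndim; ++j) {
        double cj = bias_c0[j] + ct * bias_dir[j];
        g[j] += bias_k[j] * (x[j] - cj);
      }
    }
    for (int j = 0; j < ndim; ++j) {
      if (!std::isfinite(g[j])) stop("non-finite potential gradient at step %d", t);
      x[j] += -mob * g[j] * dt + noise * norm_rand();
      if (std::fabs(x[j]) > domain_limit) diverged = true;
    }
    if (t % save_every == 0) {
      for (int j = 0; j < ndim; ++j) frames(isave, j) = x[j];
      if (bias_on) {
        double ct = bias_rate * t * dt;
        for (int j = 0; j < ndim; ++j) bias(isave, j) = bias_c0[j] + ct * bias_dir[j];
      }
      ++isave;
      if (diverged) break;  // truncate after recording the offending frame
    }
  }
  if (diverged && isave < n_save) {
    frames = frames(Range(0, isave - 1), Range(0, ndim - 1));
    if (bias_on) bias = bias(Range(0, isave - 1), Range(0, ndim - 1));
  }
  return List::create(_["frames"] = frames, _["bias"] = bias,
                      _["diverged"] = diverged);
}

// Discrete-time Markov chain sampler over a row-stochastic matrix.
// Returns 1-based state sequence of length n_steps + 1 including the start.
// [[Rcpp::export]]
IntegerVector sample_chain_cpp(NumericMatrix T, int n_steps, int start0) {
  RNGScope scope;
  int n = T.nrow();
  // row-wise cumulative probabilities
  std::vector<double> cum(n * n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < n; ++j) {
      acc += T(i, j);
      cum[i * n + j] = acc;
    }
    cum[i * n + n - 1] = 1.0;  // guard against rounding at the tail
  }
  IntegerVector out(n_steps + 1);
  int s = start0;
  out[0] = s + 1;
  for (int t = 1; t <= n_steps; ++t) {
    double u = unif_rand();
    const double* row = &cum[s * n];
    // binary search for first cum >= u
    int lo = 0, hi = n - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (row[mid] >= u) hi = mid; else lo = mid + 1;
    }
    s = lo;
    out[t] = s + 1;
  }
  return out;
}
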