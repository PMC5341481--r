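// Compiled core for the toy quadratic nucleosome model:
//  - exact Gaussian statistics (minimum energy, log-determinant) per
//    sequence via an LDL^T tridiagonal factorization,
//  - Metropolis Monte Carlo over the spatial angles of a fixed sequence,
//  - Mutation Monte Carlo (MMC) over joint (sequence, angles) space.
//
// The energy of a sequence S with step angles theta (length L-1) is
//   E = sum_n [ 0.5*K(d_n)*(theta_n - theta0(d_n))^2
//             + 0.5*kappa*(theta_n - c_n)^2 ]
//     + sum_n 0.5*lambda*(theta_{n+1} - theta_n)^2,
// with d_n the dinucleotide (4*S_n + S_{n+1}) at step n.
//
// Randomness uses a local mt19937 stream seeded explicitly, so results are
// reproducible independently of R's RNG state and identical across
// platforms (raw 32-bit draws are scaled by hand; no implementation-defined
// <random> distributions are used).

#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

static inline double runif01(std::mt19937 &g) {
  return (static_cast<double>(g()) + 0.5) * (1.0 / 4294967296.0);
}

static inline int rint_below(std::mt19937 &g, int n) {
  // unbiased enough for n <= 4 alternatives and chain lengths used here
  return static_cast<int>(runif01(g) * n) % n;
}

// Per-sequence Gaussian statistics of the quadratic energy.
// codes: n_seq x L matrix of base codes 0..3; cprof has length L-1.
// Returns n_seq x 2 matrix: column 0 = E(theta*), column 1 = log det M.
// [[Rcpp::export]]
NumericMatrix toy_gaussian_stats_cpp(IntegerMatrix codes, NumericVector K,
                                     NumericVector t0, double kappa,
                                     NumericVector cprof, double lambda) {
  const int nseq = codes.nrow();
  const int L = codes.ncol();
  const int ns = L - 1;  // number of steps
  if (cprof.size() != ns) stop("cprof length must be L - 1");
  NumericMatrix out(nseq, 2);
  std::vector<double> diag(ns), b(ns), d(ns), y(ns), theta(ns);
  for (int i = 0; i < nseq; ++i) {
    double c0 = 0.0;
    for (int n = 0; n < ns; ++n) {
      int dn = 4 * codes(i, n) + codes(i, n + 1);
      double Kn = K[dn], t0n = t0[dn], cn = cprof[n];
      diag[n] = Kn + kappa;
      b[n] = Kn * t0n + kappa * cn;
      c0 += 0.5 * Kn * t0n * t0n + 0.5 * kappa * cn * cn;
    }
    if (lambda > 0.0 && ns >= 2) {
      diag[0] += lambda;
      diag[ns - 1] += lambda;
      for (int n = 1; n < ns - 1; ++n) diag[n] += 2.0 * lambda;
    }
    // LDL^T factorization of the symmetric tridiagonal M (off-diag -lambda)
    double logdet = 0.0;
    d[0] = diag[0];
    y[0] = b[0];
    logdet += std::log(d[0]);
    for (int n = 1; n < ns; ++n) {
      d[n] = diag[n] - lambda * lambda / d[n - 1];
      y[n] = b[n] + lambda / d[n - 1] * y[n - 1];
      logdet += std::log(d[n]);
    }
    theta[ns - 1] = y[ns - 1] / d[ns - 1];
    for (int n = ns - 2; n >= 0; --n)
      theta[n] = (y[n] + lambda * theta[n + 1]) / d[n];
    double bdot = 0.0;
    for (int n = 0; n < ns; ++n) bdot += b[n] * theta[n];
    out(i, 0) = c0 - 0.5 * bdot;  // E(theta*)
    out(i, 1) = logdet;
  }
  return out;
}

static inline double step_energy(double th, double Kn, double t0n,
                                 double kappa, double cn) {
  double a = th - t0n, c = th - cn;
  return 0.5 * Kn * a * a + 0.5 * kappa * c * c;
}

static double total_energy(const std::vector<int> &seq,
                           const std::vector<double> &theta,
                           const NumericVector &K, const NumericVector &t0,
                           double kappa, const NumericVector &cprof,
                           double lambda) {
  const int ns = (int)theta.size();
  double E = 0.0;
  for (int n = 0; n < ns; ++n) {
    int dn = 4 * seq[n] + seq[n + 1];
    E += step_energy(theta[n], K[dn], t0[dn], kappa, cprof[n]);
  }
  for (int n = 0; n + 1 < ns; ++n) {
    double dd = theta[n + 1] - theta[n];
    E += 0.5 * lambda * dd * dd;
  }
  return E;
}

// One Metropolis spatial move on step n; returns 1 if accepted.
static inline int spatial_move(std::vector<int> &seq,
                               std::vector<double> &theta, int n,
                               const NumericVector &K, const NumericVector &t0,
                               double kappa, const NumericVector &cprof,
                               double lambda, double beta, double delta,
                               std::mt19937 &g) {
  const int ns = (int)theta.size();
  int dn = 4 * seq[n] + seq[n + 1];
  double old_th = theta[n];
  double new_th = old_th + (2.0 * runif01(g) - 1.0) * delta;
  double dE = step_energy(new_th, K[dn], t0[dn], kappa, cprof[n]) -
              step_energy(old_th, K[dn], t0[dn], kappa, cprof[n]);
  if (lambda > 0.0) {
    if (n > 0) {
      double a = new_th - theta[n - 1], b = old_th - theta[n - 1];
      dE += 0.5 * lambda * (a * a - b * b);
    }
    if (n + 1 < ns) {
      double a = theta[n + 1] - new_th, b = theta[n + 1] - old_th;
      dE += 0.5 * lambda * (a * a - b * b);
    }
  }
  if (dE <= 0.0 || runif01(g) < std::exp(-beta * dE)) {
    theta[n] = new_th;
    return 1;
  }
  return 0;
}

// Sample the Boltzmann sequence distribution by Mutation Monte Carlo.
// Returns an n_samples x L integer matrix of base codes.
// [[Rcpp::export]]
IntegerMatrix mmc_sample_cpp(int L, NumericVector K, NumericVector t0,
                             double kappa, NumericVector cprof, double lambda,
                             double beta, double mutation_fraction,
                             double delta, int n_samples, int burn_sweeps,
                             int thin_sweeps, int seed) {
  const int ns = L - 1;
  if (cprof.size() != ns) stop("cprof length must be L - 1");
  std::mt19937 g(static_cast<uint32_t>(seed));
  std::vector<int> seq(L);
  std::vector<double> theta(ns, 0.0);
  for (int i = 0; i < L; ++i) seq[i] = rint_below(g, 4);

  IntegerMatrix out(n_samples, L);
  long long moves_per_sweep = L;
  long long total_sweeps =
      (long long)burn_sweeps + (long long)n_samples * thin_sweeps;
  int recorded = 0;
  for (long long sw = 0; sw < total_sweeps; ++sw) {
    for (long long mv = 0; mv < moves_per_sweep; ++mv) {
      if (runif01(g) < mutation_fraction) {
        // mutate one base to one of the 3 alternatives (symmetric proposal)
        int i = rint_below(g, L);
        int old_b = seq[i];
        int new_b = (old_b + 1 + rint_below(g, 3)) % 4;
        double dE = 0.0;
        if (i > 0) {  // step i-1: dinucleotide (i-1, i)
          int d_old = 4 * seq[i - 1] + old_b;
          int d_new = 4 * seq[i - 1] + new_b;
          dE += step_energy(theta[i - 1], K[d_new], t0[d_new], kappa,
                            cprof[i - 1]) -
                step_energy(theta[i - 1], K[d_old], t0[d_old], kappa,
                            cprof[i - 1]);
        }
        if (i < ns) {  // step i: dinucleotide (i, i+1)
          int d_old = 4 * old_b + seq[i + 1];
          int d_new = 4 * new_b + seq[i + 1];
          dE += step_energy(theta[i], K[d_new], t0[d_new], kappa, cprof[i]) -
                step_energy(theta[i], K[d_old], t0[d_old], kappa, cprof[i]);
        }
        if (dE <= 0.0 || runif01(g) < std::exp(-beta * dE)) seq[i] = new_b;
      } else {
        int n = rint_below(g, ns);
        spatial_move(seq, theta, n, K, t0, kappa, cprof, lambda, beta, delta,
                     g);
      }
    }
    if (sw >= burn_sweeps &&
        (sw - burn_sweeps + 1) % thin_sweeps == 0 && recorded < n_samples) {
      for (int i = 0; i < L; ++i) out(recorded, i) = seq[i];
      ++recorded;
    }
  }
  if (recorded != n_samples) stop("internal error: recorded != n_samples");
  return out;
}

// Plain (spatial-only) Metropolis chain for a fixed sequence; returns the
// total energy sampled every `thin_sweeps` sweeps after burn-in.
// [[Rcpp::export]]
NumericVector mc_energy_samples_cpp(IntegerVector seq_codes, NumericVector K,
                                    NumericVector t0, double kappa,
                                    NumericVector cprof, double lambda,
                                    double beta, double delta, int n_samples,
                                    int burn_sweeps, int thin_sweeps,
                                    int seed) {
  const int L = seq_codes.size();
  const int ns = L - 1;
  if (cprof.size() != ns) stop("cprof length must be L - 1");
  std::mt19937 g(static_cast<uint32_t>(seed));
  std::vector<int> seq(seq_codes.begin(), seq_codes.end());
  std::vector<double> theta(ns, 0.0);
  NumericVector out(n_samples);
  long long total_sweeps =
      (long long)burn_sweeps + (long long)n_samples * thin_sweeps;
  int recorded = 0;
  for (long long sw = 0; sw < total_sweeps; ++sw) {
    for (int mv = 0; mv < ns; ++mv) {
      int n = rint_below(g, ns);
      spatial_move(seq, theta, n, K, t0, kappa, cprof, lambda, beta, delta, g);
    }
    if (sw >= burn_sweeps &&
        (sw - burn_sweeps + 1) % thin_sweeps == 0 && recorded < n_samples) {
      out[recorded++] =
          total_energy(seq, theta, K, t0, kappa, cprof, lambda);
    }
  }
  if (recorded != n_samples) stop("internal error: recorded != n_samples");
  return out;
}
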