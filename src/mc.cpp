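#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

// Metropolis Monte Carlo of a point-particle fluid: single-particle
// displacement moves under minimum-image Lennard-Jones (Lorentz-Berthelot
// combination) plus truncated Coulomb in a periodic orthorhombic box,
// optionally with a fixed hard-sphere solute at the origin.  Produces an
// equilibrium ensemble, which is exactly what the voxel analysis consumes;
// no integrator or thermostat is involved.
//
// Deterministic for a fixed seed (std::mt19937 throughout).

static double pair_e(const std::vector<double> &x, int i, int j,
                     const NumericVector &q, const NumericVector &sig,
                     const NumericVector &eps, const double *L, double cut2,
                     double coul) {
  double r2 = 0.0;
  for (int d = 0; d < 3; ++d) {
    double dx = x[3 * i + d] - x[3 * j + d];
    dx -= L[d] * std::round(dx / L[d]);
    r2 += dx * dx;
  }
  if (r2 > cut2) return 0.0;
  double r = std::sqrt(r2), e = 0.0;
  double qq = q[i] * q[j];
  if (qq != 0.0) e += coul * qq / r;
  double eij = std::sqrt(eps[i] * eps[j]);
  if (eij != 0.0) {
    double sij = 0.5 * (sig[i] + sig[j]);
    double sr6 = std::pow(sij * sij / r2, 3.0);
    e += 4.0 * eij * (sr6 * sr6 - sr6);
  }
  return e;
}

static double one_particle_e(const std::vector<double> &x, int i, int n,
                             const NumericVector &q, const NumericVector &sig,
                             const NumericVector &eps, const double *L,
                             double cut2, double coul) {
  double e = 0.0;
  for (int j = 0; j < n; ++j)
    if (j != i) e += pair_e(x, i, j, q, sig, eps, L, cut2, coul);
  return e;
}

static inline double origin_dist(const std::vector<double> &x, int i,
                                 const double *L) {
  double s = 0.0;
  for (int d = 0; d < 3; ++d) {
    double dx = x[3 * i + d];
    dx -= L[d] * std::round(dx / L[d]);
    s += dx * dx;
  }
  return std::sqrt(s);
}

// [[Rcpp::export]]
List cpp_mc_fluid(NumericMatrix X0, NumericVector box, NumericVector charge,
                  NumericVector sigma, NumericVector eps, double cutoff,
                  double beta, double max_disp, int n_equil_sweeps,
                  int n_frames, int stride_sweeps, double solute_radius,
                  int seed) {
  int n = X0.nrow();
  double L[3] = {box[0], box[1], box[2]};
  double cut2 = cutoff * cutoff, coul = 332.0637;
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = X0(i, d);

  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  std::uniform_int_distribution<int> pick(0, n - 1);

  long accepted = 0, attempted = 0;
  int total_sweeps = n_equil_sweeps + n_frames * stride_sweeps;
  NumericVector frames((R_xlen_t)n_frames * n * 3);
  NumericVector frame_energy(n_frames);
  int stored = 0;

  for (int sweep = 0; sweep < total_sweeps; ++sweep) {
    for (int mv = 0; mv < n; ++mv) {
      int i = pick(rng);
      double old_e = one_particle_e(x, i, n, charge, sigma, eps, L, cut2,
                                    coul);
      double save[3];
      for (int d = 0; d < 3; ++d) {
        save[d] = x[3 * i + d];
        double p = save[d] + max_disp * (2.0 * U(rng) - 1.0);
        p -= L[d] * std::floor((p + L[d] / 2.0) / L[d]);  // wrap to [-L/2,L/2)
        x[3 * i + d] = p;
      }
      ++attempted;
      bool reject = false;
      if (solute_radius > 0.0 && origin_dist(x, i, L) < solute_radius)
        reject = true;
      if (!reject) {
        double new_e = one_particle_e(x, i, n, charge, sigma, eps, L, cut2,
                                      coul);
        double dE = new_e - old_e;
        if (dE > 0.0 && U(rng) >= std::exp(-beta * dE)) reject = true;
      } else {
        U(rng);  // keep the random stream aligned across accept paths
      }
      if (reject) {
        for (int d = 0; d < 3; ++d) x[3 * i + d] = save[d];
      } else {
        ++accepted;
      }
    }
    int prod = sweep - n_equil_sweeps + 1;
    if (prod > 0 && prod % stride_sweeps == 0 && stored < n_frames) {
      double etot = 0.0;
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
          etot += pair_e(x, i, j, charge, sigma, eps, L, cut2, coul);
      frame_energy[stored] = etot;
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          frames[(R_xlen_t)stored * n * 3 + 3 * i + d] = x[3 * i + d];
      ++stored;
    }
  }
  return List::create(_["frames"] = frames, _["n_stored"] = stored,
                      _["acceptance"] = (double)accepted / attempted,
                      _["frame_energy"] = frame_energy);
}

// Uniform random initial placement that respects the hard-sphere solute,
// drawn from the same deterministic generator family as the sampler.
// [[Rcpp::export]]
NumericMatrix cpp_mc_init(int n, NumericVector box, double solute_radius,
                          int seed) {
  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  NumericMatrix X(n, 3);
  double L[3] = {box[0], box[1], box[2]};
  for (int i = 0; i < n; ++i) {
    for (int tries = 0; tries < 10000; ++tries) {
      double p[3], r2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        p[d] = (U(rng) - 0.5) * L[d];
        r2 += p[d] * p[d];
      }
      if (solute_radius > 0.0 && std::sqrt(r2) < solute_radius) continue;
      for (int d = 0; d < 3; ++d) X(i, d) = p[d];
      break;
    }
  }
  return X;
}
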