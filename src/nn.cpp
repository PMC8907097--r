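#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Nearest-neighbor search over solvent samples pooled across frames.
// Metrics: translational (minimum-image Euclidean), orientational
// (geodesic rotation angle), and the joint six-dimensional metric
// sqrt(dw^2 + dr^2).  Exact: a cell list over positions is scanned with a
// growing search radius until the best candidate distance is covered by the
// scanned radius; the joint metric is bounded below by the translational
// distance, which makes the same stopping rule exact for it as well.

struct CellList {
  int nc[3];
  double w[3], lo[3], L[3];
  bool periodic;
  std::vector<std::vector<int> > cells;

  void build(const NumericMatrix &X, const NumericVector &box,
             bool periodic_, double target_per_cell = 2.0) {
    periodic = periodic_;
    int n = X.nrow();
    double span[3];
    for (int d = 0; d < 3; ++d) {
      if (periodic) {
        L[d] = box[d];
        lo[d] = -box[d] / 2.0;
        span[d] = box[d];
      } else {
        double mn = X(0, d), mx = X(0, d);
        for (int i = 1; i < n; ++i) {
          mn = std::min(mn, X(i, d));
          mx = std::max(mx, X(i, d));
        }
        lo[d] = mn;
        span[d] = std::max(mx - mn, 1e-9);
        L[d] = span[d];
      }
    }
    double vol = span[0] * span[1] * span[2];
    double cw = std::cbrt(vol * target_per_cell / std::max(n, 1));
    long total = 1;
    for (int d = 0; d < 3; ++d) {
      nc[d] = std::max(1, (int)std::floor(span[d] / std::max(cw, 1e-9)));
      nc[d] = std::min(nc[d], 128);
      w[d] = span[d] / nc[d];
      total *= nc[d];
    }
    cells.assign(total, std::vector<int>());
    for (int i = 0; i < n; ++i)
      cells[cell_of(X(i, 0), X(i, 1), X(i, 2))].push_back(i);
  }

  inline int idx1(int ix, int iy, int iz) const {
    return ix + nc[0] * (iy + nc[1] * iz);
  }
  inline int wrap(int i, int d) const {
    int m = i % nc[d];
    return m < 0 ? m + nc[d] : m;
  }
  inline int clampi(int i, int d) const {
    return std::max(0, std::min(nc[d] - 1, i));
  }
  int cell_of(double x, double y, double z) const {
    double p[3] = {x, y, z};
    int c[3];
    for (int d = 0; d < 3; ++d) {
      int i = (int)std::floor((p[d] - lo[d]) / w[d]);
      c[d] = periodic ? wrap(i, d) : clampi(i, d);
    }
    return idx1(c[0], c[1], c[2]);
  }
};

static inline double dist2_mi(const NumericMatrix &X, int i, int j,
                              const double *L, bool periodic) {
  double s = 0.0;
  for (int d = 0; d < 3; ++d) {
    double dx = X(i, d) - X(j, d);
    if (periodic) dx -= L[d] * std::round(dx / L[d]);
    s += dx * dx;
  }
  return s;
}

static inline double dw_quat(const NumericMatrix &Q, int i, int j) {
  double dot = 0.0;
  for (int k = 0; k < 4; ++k) dot += Q(i, k) * Q(j, k);
  dot = std::fabs(dot);
  if (dot > 1.0) dot = 1.0;
  return 2.0 * std::acos(dot);
}

// Scan all samples in cells overlapping the cube of half-width r around
// query i; callback receives candidate index j (j != i).
template <typename F>
static void scan_radius(const CellList &cl, const NumericMatrix &X, int i,
                        double r, F f) {
  int rng[3][2];
  bool full[3];
  for (int d = 0; d < 3; ++d) {
    int lo_c = (int)std::floor((X(i, d) - r - cl.lo[d]) / cl.w[d]);
    int hi_c = (int)std::floor((X(i, d) + r - cl.lo[d]) / cl.w[d]);
    full[d] = (hi_c - lo_c + 1) >= cl.nc[d];
    if (full[d]) { lo_c = 0; hi_c = cl.nc[d] - 1; }
    else if (!cl.periodic) {
      lo_c = cl.clampi(lo_c, d);
      hi_c = cl.clampi(hi_c, d);
    }
    rng[d][0] = lo_c; rng[d][1] = hi_c;
  }
  for (int iz = rng[2][0]; iz <= rng[2][1]; ++iz) {
    int cz = cl.periodic && !full[2] ? cl.wrap(iz, 2) : iz;
    for (int iy = rng[1][0]; iy <= rng[1][1]; ++iy) {
      int cy = cl.periodic && !full[1] ? cl.wrap(iy, 1) : iy;
      for (int ix = rng[0][0]; ix <= rng[0][1]; ++ix) {
        int cx = cl.periodic && !full[0] ? cl.wrap(ix, 0) : ix;
        const std::vector<int> &cell = cl.cells[cl.idx1(cx, cy, cz)];
        for (size_t t = 0; t < cell.size(); ++t)
          if (cell[t] != i) f(cell[t]);
      }
    }
  }
}

// Translational nearest-neighbor distances (minimum image when periodic),
// excluding the identical sample, for the 0-based rows in `query`.
// [[Rcpp::export]]
NumericVector cpp_nn_trans(NumericMatrix X, NumericVector box, bool periodic,
                           IntegerVector query) {
  int n = X.nrow(), nq = query.size();
  NumericVector out(nq);
  if (n < 2) { std::fill(out.begin(), out.end(), NA_REAL); return out; }
  CellList cl;
  cl.build(X, box, periodic);
  double vol = cl.L[0] * cl.L[1] * cl.L[2];
  double r0 = 1.3 * std::cbrt(vol / n);
  double rmax = std::sqrt(cl.L[0] * cl.L[0] + cl.L[1] * cl.L[1] +
                          cl.L[2] * cl.L[2]);
  for (int t = 0; t < nq; ++t) {
    int i = query[t];
    double r = r0, best = R_PosInf;
    while (true) {
      double best2 = R_PosInf;
      scan_radius(cl, X, i, r, [&](int j) {
        double d2 = dist2_mi(X, i, j, cl.L, periodic);
        if (d2 < best2) best2 = d2;
      });
      best = std::sqrt(best2);
      if (best <= r || r > rmax) break;
      r = std::max(r * 1.7, best <= r * 4 ? best : r * 1.7);
    }
    out[t] = best;
  }
  return out;
}

// Six-dimensional nearest neighbor: minimizes sqrt(dw^2 + dr^2) jointly.
// Exact because dr <= metric value, so once the scan radius covers the best
// joint value no unscanned candidate can improve on it (dw is additionally
// bounded by pi).
// [[Rcpp::export]]
NumericVector cpp_nn_six(NumericMatrix X, NumericMatrix Q, NumericVector box,
                         bool periodic, IntegerVector query) {
  int n = X.nrow(), nq = query.size();
  NumericVector out(nq);
  if (n < 2) { std::fill(out.begin(), out.end(), NA_REAL); return out; }
  CellList cl;
  cl.build(X, box, periodic);
  double vol = cl.L[0] * cl.L[1] * cl.L[2];
  double r0 = 1.3 * std::cbrt(vol / n);
  double rmax = std::sqrt(cl.L[0] * cl.L[0] + cl.L[1] * cl.L[1] +
                          cl.L[2] * cl.L[2]) + M_PI;
  for (int t = 0; t < nq; ++t) {
    int i = query[t];
    double r = r0, best = R_PosInf;
    while (true) {
      double b = best;
      scan_radius(cl, X, i, r, [&](int j) {
        double d2 = dist2_mi(X, i, j, cl.L, periodic);
        if (d2 >= b * b) return;  // dr alone already too large
        double dw = dw_quat(Q, i, j);
        double six = std::sqrt(d2 + dw * dw);
        if (six < b) b = six;
      });
      best = b;
      if (best <= r || r > rmax) break;
      r *= 1.7;
    }
    out[t] = best;
  }
  return out;
}

// Orientational nearest neighbor within groups (voxels): for each sample,
// the minimal rotation angle to any other sample of the same group.
// group is 0-based; samples with group < 0 are skipped.  Returns NA for
// skipped samples and for groups of size < 2.
// [[Rcpp::export]]
NumericVector cpp_nn_orient_groups(NumericMatrix Q, IntegerVector group,
                                   int n_groups) {
  int n = Q.nrow();
  NumericVector out(n, NA_REAL);
  std::vector<std::vector<int> > g(n_groups);
  for (int i = 0; i < n; ++i)
    if (group[i] >= 0 && group[i] < n_groups) g[group[i]].push_back(i);
  for (int k = 0; k < n_groups; ++k) {
    const std::vector<int> &m = g[k];
    if (m.size() < 2) continue;
    for (size_t a = 0; a < m.size(); ++a) {
      double best = R_PosInf;
      for (size_t b = 0; b < m.size(); ++b) {
        if (a == b) continue;
        double dw = dw_quat(Q, m[a], m[b]);
        if (dw < best) best = dw;
      }
      out[m[a]] = best;
    }
  }
  return out;
}
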