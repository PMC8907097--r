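#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double mi_dist(const NumericMatrix &A, int i,
                             const NumericMatrix &B, int j,
                             const NumericVector &box) {
  double s = 0.0;
  for (int d = 0; d < 3; ++d) {
    double dx = A(i, d) - B(j, d);
    dx -= box[d] * std::round(dx / box[d]);
    s += dx * dx;
  }
  return std::sqrt(s);
}

// Per-voxel radial pair histogram for one frame, accumulated in place.
//
// X1: positions of species nu with voxel assignment vox1 (0-based, -1 =
// outside the coarse grid, skipped).  X2: all positions of species nu' in
// the box.  selfmap[i] gives the row of X2 holding the same molecule as
// X1 row i (-1 if none), excluded from its own histogram.
// acc is a K x nbins matrix (K coarse voxels).  Returns the number of pairs
// histogrammed (nu inside the grid, distance < nbins*dd), for conservation
// checks.
// [[Rcpp::export]]
double cpp_pair_hist(NumericMatrix X1, IntegerVector vox1, NumericMatrix X2,
                     IntegerVector selfmap, NumericVector box, double dd,
                     int nbins, NumericMatrix acc) {
  int n1 = X1.nrow(), n2 = X2.nrow();
  double rmax = dd * nbins, count = 0.0;
  for (int i = 0; i < n1; ++i) {
    int k = vox1[i];
    if (k < 0) continue;
    for (int j = 0; j < n2; ++j) {
      if (j == selfmap[i]) continue;
      double r = mi_dist(X1, i, X2, j, box);
      if (r >= rmax) continue;
      int l = (int)(r / dd);
      acc(k, l) += 1.0;
      count += 1.0;
    }
  }
  return count;
}

// Bulk radial pair histogram for one frame (no voxel resolution):
// X1 are the nu molecules selected as bulk-like, X2 all nu' molecules.
// [[Rcpp::export]]
double cpp_bulk_hist(NumericMatrix X1, NumericMatrix X2, IntegerVector selfmap,
                     NumericVector box, double dd, int nbins,
                     NumericVector acc) {
  int n1 = X1.nrow(), n2 = X2.nrow();
  double rmax = dd * nbins, count = 0.0;
  for (int i = 0; i < n1; ++i) {
    for (int j = 0; j < n2; ++j) {
      if (j == selfmap[i]) continue;
      double r = mi_dist(X1, i, X2, j, box);
      if (r >= rmax) continue;
      acc[(int)(r / dd)] += 1.0;
      count += 1.0;
    }
  }
  return count;
}

// Spherical-shell sums of a fine density grid around each coarse-voxel
// center.  The fine grid (values relative to the bulk density) covers the
// periodic box exactly when `periodic`; otherwise cells beyond the stored
// fine grid take the bulk value 1.0.  Shells are radial bins of width dd on
// the distance between the voxel center and the fine-cell centers; returns
// per-shell value sums and cell counts (K x nbins each) so callers can pool
// under-supported shells before taking means.
// `fine` holds one column per species over the same lattice, so the
// distance/bin geometry is computed once for all of them.
// [[Rcpp::export]]
List cpp_shell_density(NumericMatrix fine, IntegerVector fdims,
                       NumericVector fspacing, NumericVector forigin,
                       NumericMatrix centers, double dd, int nbins,
                       bool periodic) {
  int K = centers.nrow();
  int ns = fine.ncol();
  int nx = fdims[0], ny = fdims[1], nz = fdims[2];
  double rmax = dd * nbins;
  List osums(ns);
  std::vector<NumericMatrix> osum;
  for (int s = 0; s < ns; ++s) {
    osum.push_back(NumericMatrix(K, nbins));
    osums[s] = osum[s];
  }
  NumericMatrix ocnt(K, nbins);
  std::vector<double> sum(nbins * ns), cnt(nbins);
  double L[3] = {nx * fspacing[0], ny * fspacing[1], nz * fspacing[2]};
  for (int k = 0; k < K; ++k) {
    std::fill(sum.begin(), sum.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0.0);
    double c[3] = {centers(k, 0), centers(k, 1), centers(k, 2)};
    int lo[3], hi[3];
    bool full[3];
    for (int d = 0; d < 3; ++d) {
      lo[d] = (int)std::floor((c[d] - rmax - forigin[d]) / fspacing[d]) - 1;
      hi[d] = (int)std::floor((c[d] + rmax - forigin[d]) / fspacing[d]) + 1;
      int n_d = d == 0 ? nx : (d == 1 ? ny : nz);
      full[d] = (hi[d] - lo[d] + 1) >= n_d;
      if (full[d] && periodic) { lo[d] = 0; hi[d] = n_d - 1; }
    }
    for (int iz = lo[2]; iz <= hi[2]; ++iz) {
      double pz = forigin[2] + (iz + 0.5) * fspacing[2];
      double dz = pz - c[2];
      if (periodic) dz -= L[2] * std::round(dz / L[2]);
      int jz = iz;
      if (periodic) { jz = iz % nz; if (jz < 0) jz += nz; }
      bool oz = jz < 0 || jz >= nz;
      for (int iy = lo[1]; iy <= hi[1]; ++iy) {
        double py = forigin[1] + (iy + 0.5) * fspacing[1];
        double dy = py - c[1];
        if (periodic) dy -= L[1] * std::round(dy / L[1]);
        int jy = iy;
        if (periodic) { jy = iy % ny; if (jy < 0) jy += ny; }
        bool oy = jy < 0 || jy >= ny;
        double dyz2 = dy * dy + dz * dz;
        if (dyz2 >= rmax * rmax) continue;
        for (int ix = lo[0]; ix <= hi[0]; ++ix) {
          double px = forigin[0] + (ix + 0.5) * fspacing[0];
          double dx = px - c[0];
          if (periodic) dx -= L[0] * std::round(dx / L[0]);
          double r2 = dx * dx + dyz2;
          if (r2 >= rmax * rmax) continue;
          int jx = ix;
          if (periodic) { jx = ix % nx; if (jx < 0) jx += nx; }
          bool outg = oz || oy || jx < 0 || jx >= nx;
          int l = (int)(std::sqrt(r2) / dd);
          cnt[l] += 1.0;
          if (outg) {
            for (int s = 0; s < ns; ++s) sum[l * ns + s] += 1.0;
          } else {
            long cell = jx + nx * (jy + (long)ny * jz);
            for (int s = 0; s < ns; ++s) sum[l * ns + s] += fine(cell, s);
          }
        }
      }
    }
    for (int l = 0; l < nbins; ++l) {
      ocnt(k, l) = cnt[l];
      for (int s = 0; s < ns; ++s) osum[s](k, l) = sum[l * ns + s];
    }
  }
  return List::create(_["sum"] = osums, _["cnt"] = ocnt);
}

// Adaptive radial pooling of shell sums: for each voxel and bin, expand a
// symmetric window of neighboring bins until at least thr_cells fine cells
// support the estimate, then report the pooled mean and the supporting cell
// count.  Bins of rows with no cells at all come out NaN / 0.
// [[Rcpp::export]]
List cpp_pool_shells(NumericMatrix sum, NumericMatrix cnt, double thr_cells) {
  int K = sum.nrow(), nb = sum.ncol();
  NumericMatrix G(K, nb), cells(K, nb);
  for (int k = 0; k < K; ++k) {
    for (int l = 0; l < nb; ++l) {
      double s = sum(k, l), c = cnt(k, l);
      int w = 0;
      while (c < thr_cells && w < nb) {
        ++w;
        if (l - w >= 0) { s += sum(k, l - w); c += cnt(k, l - w); }
        if (l + w < nb) { s += sum(k, l + w); c += cnt(k, l + w); }
      }
      if (c > 0) { G(k, l) = s / c; cells(k, l) = c; }
      else { G(k, l) = NA_REAL; cells(k, l) = 0.0; }
    }
  }
  return List::create(_["G"] = G, _["cells"] = cells);
}

// Fine-grid occupancy: increments cell counts for positions wrapped into
// the periodic box.  acc has length nx*ny*nz (x fastest).
// [[Rcpp::export]]
void cpp_bin_positions(NumericMatrix X, IntegerVector fdims,
                       NumericVector fspacing, NumericVector forigin,
                       NumericVector acc) {
  int nx = fdims[0], ny = fdims[1], nz = fdims[2];
  for (int i = 0; i < X.nrow(); ++i) {
    int c[3];
    for (int d = 0; d < 3; ++d) {
      int n_d = d == 0 ? nx : (d == 1 ? ny : nz);
      int j = (int)std::floor((X(i, d) - forigin[d]) / fspacing[d]);
      j %= n_d;
      if (j < 0) j += n_d;
      c[d] = j;
    }
    acc[c[0] + nx * (c[1] + (long)ny * c[2])] += 1.0;
  }
}
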