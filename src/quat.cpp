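#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Jacobi eigen-decomposition of a symmetric 4x4 matrix; returns the
// eigenvector of the largest eigenvalue.  Small fixed-size problem, so a
// handful of cyclic sweeps converges to machine precision.
static void max_eigvec4(double A[4][4], double v[4]) {
  double V[4][4] = {{1, 0, 0, 0}, {0, 1, 0, 0}, {0, 0, 1, 0}, {0, 0, 0, 1}};
  for (int sweep = 0; sweep < 50; ++sweep) {
    double off = 0.0;
    for (int p = 0; p < 4; ++p)
      for (int q = p + 1; q < 4; ++q) off += A[p][q] * A[p][q];
    if (off < 1e-30) break;
    for (int p = 0; p < 4; ++p) {
      for (int q = p + 1; q < 4; ++q) {
        if (std::fabs(A[p][q]) < 1e-300) continue;
        double theta = (A[q][q] - A[p][p]) / (2.0 * A[p][q]);
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < 4; ++k) {
          double akp = A[k][p], akq = A[k][q];
          A[k][p] = c * akp - s * akq;
          A[k][q] = s * akp + c * akq;
        }
        for (int k = 0; k < 4; ++k) {
          double apk = A[p][k], aqk = A[q][k];
          A[p][k] = c * apk - s * aqk;
          A[q][k] = s * apk + c * aqk;
        }
        for (int k = 0; k < 4; ++k) {
          double vkp = V[k][p], vkq = V[k][q];
          V[k][p] = c * vkp - s * vkq;
          V[k][q] = s * vkp + c * vkq;
        }
      }
    }
  }
  int best = 0;
  for (int k = 1; k < 4; ++k) if (A[k][k] > A[best][best]) best = k;
  for (int k = 0; k < 4; ++k) v[k] = V[k][best];
}

// Best-fit rotation (Horn's quaternion method) mapping the reference water
// geometry (hydrogens ref1/ref2 relative to the oxygen) onto the observed
// geometry, per molecule.  cidx/o1/o2 are 0-based atom row indices of the
// center atom and the two reference hydrogens.
// [[Rcpp::export]]
NumericMatrix cpp_water_quats(NumericMatrix xyz, IntegerVector cidx,
                              IntegerVector o1, IntegerVector o2,
                              NumericVector ref1, NumericVector ref2) {
  int n = cidx.size();
  NumericMatrix out(n, 4);
  for (int m = 0; m < n; ++m) {
    double a[3], b[3];
    for (int k = 0; k < 3; ++k) {
      a[k] = xyz(o1[m], k) - xyz(cidx[m], k);
      b[k] = xyz(o2[m], k) - xyz(cidx[m], k);
    }
    // collinearity check on the observed O-H vectors
    double cx = a[1] * b[2] - a[2] * b[1];
    double cy = a[2] * b[0] - a[0] * b[2];
    double cz = a[0] * b[1] - a[1] * b[0];
    double na = std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
    double nb = std::sqrt(b[0] * b[0] + b[1] * b[1] + b[2] * b[2]);
    if (std::sqrt(cx * cx + cy * cy + cz * cz) < 1e-8 * na * nb)
      stop("degenerate (collinear) water geometry at molecule row %d", m + 1);
    // S_ab = sum_i ref_a * obs_b over the two point pairs
    double S[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        S[i][j] = ref1[i] * a[j] + ref2[i] * b[j];
    double N[4][4];
    N[0][0] =  S[0][0] + S[1][1] + S[2][2];
    N[0][1] =  S[1][2] - S[2][1];
    N[0][2] =  S[2][0] - S[0][2];
    N[0][3] =  S[0][1] - S[1][0];
    N[1][1] =  S[0][0] - S[1][1] - S[2][2];
    N[1][2] =  S[0][1] + S[1][0];
    N[1][3] =  S[2][0] + S[0][2];
    N[2][2] = -S[0][0] + S[1][1] - S[2][2];
    N[2][3] =  S[1][2] + S[2][1];
    N[3][3] = -S[0][0] - S[1][1] + S[2][2];
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < i; ++j) N[i][j] = N[j][i];
    double q[4];
    max_eigvec4(N, q);
    double nq = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] +
                          q[3] * q[3]);
    for (int k = 0; k < 4; ++k) out(m, k) = q[k] / nq;
  }
  return out;
}
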