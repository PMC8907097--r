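#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Per-frame nonbonded energies between molecule pairs.
//
// Lennard-Jones with Lorentz-Berthelot combination (arithmetic sigma,
// geometric epsilon) plus truncated Coulomb, both cut at `cutoff` per atom
// pair.  The minimum image is applied once per molecule pair from the
// molecule centers, so a molecule's atoms stay on one periodic image.
//
// Assignment follows the GIST bookkeeping: solute-solvent pair energy goes
// wholly to the solvent molecule (E_uv); solvent-solvent pair energy is
// split half/half between both molecules (E_vv).  Division by the number of
// frames happens on the R side.
//
// mol_first/mol_last/center_atom are 0-based atom indices; species_code is
// 0 = solute, >0 = solvent.
// [[Rcpp::export]]
List cpp_frame_energies(NumericMatrix xyz, NumericVector box,
                        NumericVector charge, NumericVector sigma,
                        NumericVector eps, IntegerVector mol_first,
                        IntegerVector mol_last, IntegerVector species_code,
                        IntegerVector center_atom, double cutoff,
                        double coul) {
  int nm = mol_first.size();
  NumericVector Euv(nm), Evv(nm);
  double cut2 = cutoff * cutoff;

  // molecule bounding radius around its center atom, for early rejection
  std::vector<double> rad(nm, 0.0);
  for (int m = 0; m < nm; ++m) {
    int c = center_atom[m];
    for (int a = mol_first[m]; a <= mol_last[m]; ++a) {
      double s = 0.0;
      for (int d = 0; d < 3; ++d) {
        double dx = xyz(a, d) - xyz(c, d);
        s += dx * dx;
      }
      rad[m] = std::max(rad[m], std::sqrt(s));
    }
  }

  for (int ma = 0; ma < nm; ++ma) {
    int ca = center_atom[ma];
    for (int mb = ma + 1; mb < nm; ++mb) {
      if (species_code[ma] == 0 && species_code[mb] == 0) continue;
      int cb = center_atom[mb];
      // minimum-image shift for molecule mb, from the centers
      double shift[3], cd2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        double dx = xyz(cb, d) - xyz(ca, d);
        double w = dx - box[d] * std::round(dx / box[d]);
        shift[d] = w - dx;
        cd2 += w * w;
      }
      double reach = cutoff + rad[ma] + rad[mb];
      if (cd2 > reach * reach) continue;

      double e = 0.0;
      for (int a = mol_first[ma]; a <= mol_last[ma]; ++a) {
        for (int b = mol_first[mb]; b <= mol_last[mb]; ++b) {
          double r2 = 0.0;
          for (int d = 0; d < 3; ++d) {
            double dx = xyz(b, d) + shift[d] - xyz(a, d);
            r2 += dx * dx;
          }
          if (r2 > cut2) continue;
          if (r2 < 1e-12)
            stop("overlapping atoms (%d, %d)", a + 1, b + 1);
          double r = std::sqrt(r2);
          double qq = charge[a] * charge[b];
          if (qq != 0.0) e += coul * qq / r;
          double eij = std::sqrt(eps[a] * eps[b]);
          if (eij != 0.0) {
            double sij = 0.5 * (sigma[a] + sigma[b]);
            double sr6 = std::pow(sij * sij / r2, 3.0);
            e += 4.0 * eij * (sr6 * sr6 - sr6);
          }
        }
      }
      if (e == 0.0) continue;
      bool sa = species_code[ma] == 0, sb = species_code[mb] == 0;
      if (sa) {
        Euv[mb] += e;           // whole solute-solvent energy to the solvent
      } else if (sb) {
        Euv[ma] += e;
      } else {
        Evv[ma] += 0.5 * e;     // half/half split between solvent partners
        Evv[mb] += 0.5 * e;
      }
    }
  }
  return List::create(_["E_uv"] = Euv, _["E_vv"] = Evv);
}
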