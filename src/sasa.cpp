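#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area.
// xyz: n x 3 atom coordinates (Angstrom); radii: per-atom van der Waals radii;
// probe: solvent probe radius; npts: test points per atom (golden-section
// spiral on the sphere).  Returns per-atom accessible area in A^2.
// [[Rcpp::export]]
NumericVector cpp_sasa(const NumericMatrix& xyz, const NumericVector& radii,
                       double probe, int npts) {
  const int n = xyz.nrow();
  // golden-section spiral unit sphere points
  std::vector<double> px(npts), py(npts), pz(npts);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < npts; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / npts;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * k;
    px[k] = r * std::cos(th); py[k] = r * std::sin(th); pz[k] = z;
  }
  NumericVector area(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    const double ri = radii[i] + probe;
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double rj = radii[j] + probe;
      double dx = xyz(j, 0) - xyz(i, 0), dy = xyz(j, 1) - xyz(i, 1),
             dz = xyz(j, 2) - xyz(i, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      double rr = ri + rj;
      if (d2 < rr * rr) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < npts; ++k) {
      const double tx = xyz(i, 0) + ri * px[k], ty = xyz(i, 1) + ri * py[k],
                   tz = xyz(i, 2) + ri * pz[k];
      bool free_pt = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double rj = radii[j] + probe;
        double dx = tx - xyz(j, 0), dy = ty - xyz(j, 1), dz = tz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * acc / npts;
    if (i % 128 == 0) Rcpp::checkUserInterrupt();
  }
  return area;
}
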