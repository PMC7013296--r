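#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Nearest centerline sample for each query point, squared Euclidean distance
// in world mm. Ties resolved to the lowest seed index (strict < comparison
// while scanning in ascending index order).
// [[Rcpp::export]]
IntegerVector nearest_seed(NumericMatrix pts, NumericMatrix seeds) {
  const int n = pts.nrow(), m = seeds.nrow();
  if (m < 1) stop("at least one seed is required");
  std::vector<double> sx(m), sy(m), sz(m);
  for (int j = 0; j < m; ++j) {
    sx[j] = seeds(j, 0);
    sy[j] = seeds(j, 1);
    sz[j] = seeds(j, 2);
  }
  IntegerVector out(n);
  const double *px = &pts(0, 0), *py = &pts(0, 1), *pz = &pts(0, 2);
  for (int i = 0; i < n; ++i) {
    const double x = px[i], y = py[i], z = pz[i];
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < m; ++j) {
      const double dx = x - sx[j];
      const double dy = y - sy[j];
      const double dz = z - sz[j];
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) {
        best = d;
        bj = j;
      }
    }
    out[i] = bj + 1;
  }
  return out;
}
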