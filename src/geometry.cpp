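#include <Rcpp.h>
using namespace Rcpp;

// Point-classification kernels behind the surface-area and packing
// operators. Coordinates are assumed already canonicalised by the R layer.

// For each atom, count its sphere-sampling points (directions in `sphere`,
// one row per unit vector) that are not inside the probe-expanded sphere of
// any other atom.
// [[Rcpp::export]]
IntegerVector count_exposed_points(NumericMatrix centers, NumericVector radii,
                                   NumericMatrix sphere, double probe) {
  const int na = centers.nrow(), np = sphere.nrow();
  IntegerVector out(na);
  std::vector<double> er(na);
  for (int i = 0; i < na; ++i) er[i] = radii[i] + probe;
  for (int i = 0; i < na; ++i) {
    // neighbours able to occlude atom i
    std::vector<int> nb;
    for (int j = 0; j < na; ++j) {
      if (j == i) continue;
      double dx = centers(j, 0) - centers(i, 0);
      double dy = centers(j, 1) - centers(i, 1);
      double dz = centers(j, 2) - centers(i, 2);
      double lim = er[i] + er[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    int cnt = 0;
    for (int k = 0; k < np; ++k) {
      double px = centers(i, 0) + er[i] * sphere(k, 0);
      double py = centers(i, 1) + er[i] * sphere(k, 1);
      double pz = centers(i, 2) + er[i] * sphere(k, 2);
      bool exposed = true;
      for (int j : nb) {
        double dx = px - centers(j, 0);
        double dy = py - centers(j, 1);
        double dz = pz - centers(j, 2);
        if (dx * dx + dy * dy + dz * dz < er[j] * er[j]) {
          exposed = false;
          break;
        }
      }
      if (exposed) ++cnt;
    }
    out[i] = cnt;
  }
  return out;
}

// For each point, whether it lies within `radii[j]` of any center j.
// [[Rcpp::export]]
LogicalVector points_within(NumericMatrix pts, NumericMatrix centers,
                            NumericVector radii) {
  const int np = pts.nrow(), nc = centers.nrow();
  LogicalVector out(np);
  for (int k = 0; k < np; ++k) {
    bool inside = false;
    for (int j = 0; j < nc && !inside; ++j) {
      double dx = pts(k, 0) - centers(j, 0);
      double dy = pts(k, 1) - centers(j, 1);
      double dz = pts(k, 2) - centers(j, 2);
      inside = dx * dx + dy * dy + dz * dz < radii[j] * radii[j];
    }
    out[k] = inside;
  }
  return out;
}
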