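// OR-projection (silhouette) of a binary volume into the plane of the first
// two principal axes: each output pixel casts a ray along axis 3 and reports
// whether any sample hits the mask (nearest-neighbour lookup).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// axes: 3x3 matrix, row r = unit vector of frame axis r in (z,y,x) physical
// coordinates (µm); centroid in µm; u along axis 1, v along axis 2.
// [[Rcpp::export]]
LogicalMatrix silhouette_cpp(LogicalVector mask, IntegerVector dims,
                             NumericVector spacing, NumericVector centroid,
                             NumericMatrix axes, double umin, double vmin,
                             double wmin, double wmax, int nu, int nv,
                             double px) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  LogicalMatrix out(nu, nv);
  int nw = (int)std::ceil((wmax - wmin) / px) + 1;
  for (int iv = 0; iv < nv; ++iv) {
    double v = vmin + (iv + 0.5) * px;
    for (int iu = 0; iu < nu; ++iu) {
      double u = umin + (iu + 0.5) * px;
      bool hit = false;
      for (int iw = 0; iw < nw && !hit; ++iw) {
        double w = wmin + iw * px;
        double z = centroid[0] + u * axes(0, 0) + v * axes(1, 0) + w * axes(2, 0);
        double y = centroid[1] + u * axes(0, 1) + v * axes(1, 1) + w * axes(2, 1);
        double x = centroid[2] + u * axes(0, 2) + v * axes(1, 2) + w * axes(2, 2);
        int i = (int)std::lround(z / spacing[0]);
        int j = (int)std::lround(y / spacing[1]);
        int k = (int)std::lround(x / spacing[2]);
        if (i < 0 || j < 0 || k < 0 || i >= d1 || j >= d2 || k >= d3) continue;
        hit = mask[i + (size_t)d1 * (j + (size_t)d2 * k)];
      }
      out(iu, iv) = hit;
    }
  }
  return out;
}
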