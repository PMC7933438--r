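// 3D binary-volume primitives: exact anisotropic Euclidean distance transform
// (Felzenszwalb & Huttenlocher lower-envelope scan per axis), connected
// component labelling, single-voxel morphology, and maximal-inscribed-sphere
// local thickness. All distances are in physical units (µm); arrays are R
// arrays with dim (z, y, x) in column-major layout.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform: d[p] = min_q f[q] + w2*(p-q)^2
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double w2, std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF && k == 0) { v[0] = q; z[1] = INF; continue; }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * q - 2.0 * w2 * p);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int p = 0; p < n; ++p) {
    if (f[v[0]] == INF) { d[p] = INF; continue; }
    while (z[k + 1] < p) ++k;
    int q = v[k];
    d[p] = f[q] + w2 * (p - q) * (p - q);
  }
}

static void dt_axis(std::vector<double>& D, int d1, int d2, int d3,
                    int axis, double w) {
  double w2 = w * w;
  int n = (axis == 0) ? d1 : (axis == 1) ? d2 : d3;
  std::vector<double> f(n), d(n), z(n + 1);
  std::vector<int> v(n);
  if (axis == 0) {
    for (int k = 0; k < d3; ++k)
      for (int j = 0; j < d2; ++j) {
        size_t base = (size_t)d1 * (j + (size_t)d2 * k);
        for (int i = 0; i < n; ++i) f[i] = D[base + i];
        dt1d(f, d, n, w2, v, z);
        for (int i = 0; i < n; ++i) D[base + i] = d[i];
      }
  } else if (axis == 1) {
    for (int k = 0; k < d3; ++k)
      for (int i = 0; i < d1; ++i) {
        size_t base = i + (size_t)d1 * d2 * k;
        for (int j = 0; j < n; ++j) f[j] = D[base + (size_t)d1 * j];
        dt1d(f, d, n, w2, v, z);
        for (int j = 0; j < n; ++j) D[base + (size_t)d1 * j] = d[j];
      }
  } else {
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        size_t base = i + (size_t)d1 * j;
        for (int k = 0; k < n; ++k) f[k] = D[base + (size_t)d1 * d2 * k];
        dt1d(f, d, n, w2, v, z);
        for (int k = 0; k < n; ++k) D[base + (size_t)d1 * d2 * k] = d[k];
      }
  }
}

static std::vector<double> edt_sq(const LogicalVector& set, int d1, int d2, int d3,
                                  const NumericVector& spacing) {
  size_t n = (size_t)d1 * d2 * d3;
  std::vector<double> D(n);
  for (size_t i = 0; i < n; ++i) D[i] = set[i] ? 0.0 : INF;
  dt_axis(D, d1, d2, d3, 0, spacing[0]);
  dt_axis(D, d1, d2, d3, 1, spacing[1]);
  dt_axis(D, d1, d2, d3, 2, spacing[2]);
  return D;
}

// 1D transform that also records the argmin source position per output
static void dt1d_arg(const std::vector<double>& f, std::vector<double>& d,
                     std::vector<int>& src, int n, double w2,
                     std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF && k == 0) { v[0] = q; z[1] = INF; continue; }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * q - 2.0 * w2 * p);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int p = 0; p < n; ++p) {
    if (f[v[0]] == INF) { d[p] = INF; src[p] = p; continue; }
    while (z[k + 1] < p) ++k;
    int q = v[k];
    d[p] = f[q] + w2 * (p - q) * (p - q);
    src[p] = q;
  }
}

// feature transform: squared distance to `set` plus the coordinates of the
// nearest set voxel (exact, anisotropic)
static void feature_edt(const LogicalVector& set, int d1, int d2, int d3,
                        const NumericVector& spacing, std::vector<double>& D,
                        std::vector<int>& Bz, std::vector<int>& By,
                        std::vector<int>& Bx) {
  size_t n = (size_t)d1 * d2 * d3;
  D.assign(n, INF);
  Bz.resize(n); By.resize(n); Bx.resize(n);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        size_t p = i + (size_t)d1 * (j + (size_t)d2 * k);
        if (set[p]) D[p] = 0.0;
        Bz[p] = i; By[p] = j; Bx[p] = k;
      }
  const int dims[3] = {d1, d2, d3};
  for (int axis = 0; axis < 3; ++axis) {
    int nn = dims[axis];
    double w2 = spacing[axis] * spacing[axis];
    std::vector<double> f(nn), d(nn), z(nn + 1);
    std::vector<int> v(nn), src(nn);
    std::vector<int> cz(nn), cy(nn), cx(nn);
    int o1 = (axis == 0) ? d2 : d1;
    int o2 = (axis == 2) ? d2 : d3;
    size_t s1 = (axis == 0) ? (size_t)d1 : 1;
    size_t s2 = (axis == 2) ? (size_t)d1 : (size_t)d1 * d2;
    size_t stride = (axis == 0) ? 1 : (axis == 1) ? (size_t)d1 : (size_t)d1 * d2;
    for (int b = 0; b < o2; ++b)
      for (int a = 0; a < o1; ++a) {
        size_t base = a * s1 + b * s2;
        for (int p = 0; p < nn; ++p) {
          size_t q = base + p * stride;
          f[p] = D[q];
          cz[p] = Bz[q]; cy[p] = By[q]; cx[p] = Bx[q];
        }
        dt1d_arg(f, d, src, nn, w2, v, z);
        for (int p = 0; p < nn; ++p) {
          size_t q = base + p * stride;
          D[q] = d[p];
          int s = src[p];
          Bz[q] = cz[s]; By[q] = cy[s]; Bx[q] = cx[s];
          // the source's own coordinate along this axis is s itself
          if (axis == 0) Bz[q] = s;
          else if (axis == 1) By[q] = s;
          else Bx[q] = s;
        }
      }
  }
}

// Distance (µm) from every voxel to the nearest TRUE voxel of `set`.
// [[Rcpp::export]]
NumericVector dist_to_set_cpp(LogicalVector set, IntegerVector dims,
                              NumericVector spacing) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  std::vector<double> D = edt_sq(set, d1, d2, d3, spacing);
  size_t n = (size_t)d1 * d2 * d3;
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = std::sqrt(D[i]);
  out.attr("dim") = dims;
  return out;
}

// Connected components, 6- or 26-connectivity; labels assigned in scan order
// (so the component containing the lowest linear voxel index gets label 1).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  size_t n = (size_t)d1 * d2 * d3;
  IntegerVector lab(n, 0);
  std::vector<int> off;
  std::vector<std::array<int,3>> nb;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh != 1) continue;
        nb.push_back({dz, dy, dx});
      }
  std::vector<size_t> stack;
  int next = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      size_t p = stack.back();
      stack.pop_back();
      int i = p % d1, j = (p / d1) % d2, k = p / ((size_t)d1 * d2);
      for (auto& dv : nb) {
        int ii = i + dv[0], jj = j + dv[1], kk = k + dv[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= d1 || jj >= d2 || kk >= d3)
          continue;
        size_t q = ii + (size_t)d1 * (jj + (size_t)d2 * kk);
        if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Erode or dilate by one voxel with the 6-neighbour cross element.
// [[Rcpp::export]]
LogicalVector morph_step_cpp(LogicalVector mask, IntegerVector dims, bool dilate) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  size_t n = (size_t)d1 * d2 * d3;
  LogicalVector out(n);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        size_t p = i + (size_t)d1 * (j + (size_t)d2 * k);
        bool acc = mask[p];
        if (dilate ? acc : !acc) { out[p] = acc; continue; }
        const int dzs[6] = {-1, 1, 0, 0, 0, 0};
        const int dys[6] = {0, 0, -1, 1, 0, 0};
        const int dxs[6] = {0, 0, 0, 0, -1, 1};
        for (int t = 0; t < 6; ++t) {
          int ii = i + dzs[t], jj = j + dys[t], kk = k + dxs[t];
          bool v;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= d1 || jj >= d2 || kk >= d3)
            v = false; // outside the grid counts as background
          else
            v = mask[ii + (size_t)d1 * (jj + (size_t)d2 * kk)];
          if (dilate && v) { acc = true; break; }
          if (!dilate && !v) { acc = false; break; }
        }
        out[p] = acc;
      }
  out.attr("dim") = dims;
  return out;
}

// Local thickness by maximal inscribed spheres (Hildebrand-Rüegsegger):
// thickness(p) = 2 * max{ r(q) : |p-q| <= r(q) } with r(q) the inscribed
// sphere radius at q, taken as the Euclidean distance from q to the nearest
// background voxel centre minus half the (minimum) voxel spacing — the
// centre-to-centre distance overshoots the true distance to the material
// boundary by half a voxel, so a 300 µm slab reads 300 µm, not 300 + h.
// Computed by processing radii in descending order; covering all voxels
// within r_k of the set {q : r(q) >= r_k} by one EDT per radius level. With
// max_levels >= number of distinct radii this is exact under this
// discretization rule; otherwise radii are floored onto a uniform level
// grid (conservative, error < one level step).
// [[Rcpp::export]]
NumericVector local_thickness_cpp(LogicalVector mask, IntegerVector dims,
                                  NumericVector spacing, int max_levels) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  size_t n = (size_t)d1 * d2 * d3;
  LogicalVector bg(n);
  for (size_t i = 0; i < n; ++i) bg[i] = !mask[i];
  std::vector<double> D;
  std::vector<int> Bz, By, Bx;
  feature_edt(bg, d1, d2, d3, spacing, D, Bz, By, Bx);
  double hmin = std::min(spacing[0], std::min(spacing[1], spacing[2]));
  // inscribed radius: centre-to-centre distance to the nearest background,
  // minus half a voxel along the dominant axis of that displacement (the
  // physical boundary sits half a voxel short of the background centre)
  std::vector<double> r(n, 0.0);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        size_t p = i + (size_t)d1 * (j + (size_t)d2 * k);
        if (!mask[p]) continue;
        double dz = std::fabs(i - Bz[p]) * spacing[0];
        double dy = std::fabs(j - By[p]) * spacing[1];
        double dx = std::fabs(k - Bx[p]) * spacing[2];
        double half; // dominant-axis tie precedence: z, then y, then x
        if (dz >= dy && dz >= dx) half = 0.5 * spacing[0];
        else if (dy >= dx) half = 0.5 * spacing[1];
        else half = 0.5 * spacing[2];
        r[p] = std::max(std::sqrt(D[p]) - half, 0.25 * hmin);
      }

  // distinct radius levels, descending
  std::vector<double> levels;
  {
    std::vector<double> rv;
    rv.reserve(n / 4);
    for (size_t i = 0; i < n; ++i)
      if (mask[i]) rv.push_back(r[i]);
    if (rv.empty()) {
      NumericVector out(n, 0.0);
      out.attr("dim") = dims;
      return out;
    }
    std::sort(rv.begin(), rv.end());
    rv.erase(std::unique(rv.begin(), rv.end()), rv.end());
    if ((int)rv.size() <= max_levels) {
      levels.assign(rv.rbegin(), rv.rend());
    } else {
      double lo = rv.front(), hi = rv.back();
      double step = (hi - lo) / (max_levels - 1);
      for (int t = max_levels - 1; t >= 0; --t) levels.push_back(lo + step * t);
      // floor each voxel radius onto the level grid so spheres never grow
      for (size_t i = 0; i < n; ++i) {
        if (!mask[i]) continue;
        int t = (int)std::floor((r[i] - lo) / step + 1e-12);
        if (t < 0) t = 0;
        if (t > max_levels - 1) t = max_levels - 1;
        r[i] = lo + step * t;
      }
    }
  }

  NumericVector th(n, 0.0);
  size_t remaining = 0;
  for (size_t i = 0; i < n; ++i)
    if (mask[i]) ++remaining;
  LogicalVector S(n);
  for (double rk : levels) {
    if (remaining == 0) break;
    bool any = false;
    for (size_t i = 0; i < n; ++i) {
      S[i] = mask[i] && r[i] >= rk - 1e-9;
      any = any || S[i];
    }
    if (!any) continue;
    std::vector<double> Dk = edt_sq(S, d1, d2, d3, spacing);
    // coverage keeps the centre-to-centre reach (rk + h/2 = the EDT radius),
    // so rim voxels inside the half-voxel skin of a sphere are still covered
    double reach = rk + 0.5 * hmin;
    double rk2 = reach * reach * (1.0 + 1e-12) + 1e-9;
    for (size_t i = 0; i < n; ++i) {
      if (mask[i] && th[i] == 0.0 && Dk[i] <= rk2) {
        th[i] = 2.0 * rk;
        --remaining;
      }
    }
  }
  th.attr("dim") = dims;
  return th;
}
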