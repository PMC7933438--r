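// Separable Gaussian filtering and multiscale Hessian tubularity (Frangi-type,
// bright-tube polarity) with anisotropic voxel spacing: derivative kernels are
// sampled per axis at sigma expressed in voxels, responses converted to
// physical units (µm) and scale-normalized by sigma^2.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

enum KernelKind { K_SMOOTH = 0, K_D1 = 1, K_D2 = 2 };

static std::vector<double> gauss_kernel(double sigma, int kind) {
  int rad = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double s2 = sigma * sigma;
  for (int x = -rad; x <= rad; ++x) {
    double g = std::exp(-0.5 * x * x / s2);
    if (kind == K_SMOOTH) k[x + rad] = g;
    else if (kind == K_D1) k[x + rad] = -x / s2 * g;
    else k[x + rad] = (x * x - s2) / (s2 * s2) * g;
  }
  double norm = 0.0;
  for (double v : k) norm += (kind == K_SMOOTH) ? v : 0.0;
  if (kind == K_SMOOTH) {
    for (double& v : k) v /= norm;
  } else {
    // normalize against the smoothing kernel's discrete mass and remove any
    // residual DC component from the second-derivative kernel
    double g0 = 0.0;
    for (int x = -rad; x <= rad; ++x) g0 += std::exp(-0.5 * x * x / s2);
    for (double& v : k) v /= g0;
    if (kind == K_D2) {
      double dc = 0.0;
      for (double v : k) dc += v;
      dc /= k.size();
      for (double& v : k) v -= dc;
    }
  }
  return k;
}

// convolve along one axis with reflected boundary
static void conv_axis(const std::vector<double>& in, std::vector<double>& out,
                      int d1, int d2, int d3, int axis,
                      const std::vector<double>& ker) {
  int rad = ((int)ker.size() - 1) / 2;
  int n = (axis == 0) ? d1 : (axis == 1) ? d2 : d3;
  size_t stride = (axis == 0) ? 1 : (axis == 1) ? (size_t)d1 : (size_t)d1 * d2;
  int o1 = (axis == 0) ? d2 : d1;
  int o2 = (axis == 2) ? d2 : d3;
  size_t s1 = (axis == 0) ? (size_t)d1 : 1;
  size_t s2 = (axis == 2) ? (size_t)d1 : (size_t)d1 * d2;
  std::vector<double> line(n);
  for (int b = 0; b < o2; ++b)
    for (int a = 0; a < o1; ++a) {
      size_t base = a * s1 + b * s2;
      for (int p = 0; p < n; ++p) line[p] = in[base + p * stride];
      for (int p = 0; p < n; ++p) {
        double acc = 0.0;
        for (int t = -rad; t <= rad; ++t) {
          int q = p + t;
          if (q < 0) q = -q - 1;            // reflect
          if (q >= n) q = 2 * n - q - 1;
          if (q < 0) q = 0;                 // guard for very short axes
          if (q >= n) q = n - 1;
          acc += line[q] * ker[t + rad];
        }
        out[base + p * stride] = acc;
      }
    }
}

static std::vector<double> separable(const std::vector<double>& img,
                                     int d1, int d2, int d3,
                                     const std::vector<double>& k1,
                                     const std::vector<double>& k2,
                                     const std::vector<double>& k3) {
  std::vector<double> a(img.size()), b(img.size());
  conv_axis(img, a, d1, d2, d3, 0, k1);
  conv_axis(a, b, d1, d2, d3, 1, k2);
  conv_axis(b, a, d1, d2, d3, 2, k3);
  return a;
}

// [[Rcpp::export]]
NumericVector gaussian_smooth_cpp(NumericVector vol, IntegerVector dims,
                                  NumericVector sigma_vox) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  std::vector<double> img(vol.begin(), vol.end());
  std::vector<double> out = separable(
      img, d1, d2, d3,
      gauss_kernel(sigma_vox[0], K_SMOOTH),
      gauss_kernel(sigma_vox[1], K_SMOOTH),
      gauss_kernel(sigma_vox[2], K_SMOOTH));
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = dims;
  return res;
}

// eigenvalues of a symmetric 3x3 matrix (analytic, ascending order)
static void sym_eig3(double a11, double a22, double a33,
                     double a12, double a13, double a23, double ev[3]) {
  double p1 = a12 * a12 + a13 * a13 + a23 * a23;
  if (p1 < 1e-300) {
    ev[0] = a11; ev[1] = a22; ev[2] = a33;
  } else {
    double q = (a11 + a22 + a33) / 3.0;
    double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
                (a33 - q) * (a33 - q) + 2.0 * p1;
    double p = std::sqrt(p2 / 6.0);
    double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
    double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
    double detB = b11 * (b22 * b33 - b23 * b23) - b12 * (b12 * b33 - b23 * b13) +
                  b13 * (b12 * b23 - b22 * b13);
    double r = detB / 2.0;
    if (r < -1.0) r = -1.0;
    if (r > 1.0) r = 1.0;
    double phi = std::acos(r) / 3.0;
    double e1 = q + 2.0 * p * std::cos(phi);
    double e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    double e2 = 3.0 * q - e1 - e3;
    ev[0] = e3; ev[1] = e2; ev[2] = e1; // ascending
  }
  if (ev[0] > ev[1]) std::swap(ev[0], ev[1]);
  if (ev[1] > ev[2]) std::swap(ev[1], ev[2]);
  if (ev[0] > ev[1]) std::swap(ev[0], ev[1]);
}

// Frangi vesselness at one scale. sigma_um is the Gaussian scale in physical
// µm; gamma <= 0 means "use half the maximal Hessian Frobenius norm". The
// structureness constant is floored at noise_mult times the median absolute
// deviation of the Hessian norm so that noise-only volumes (where the
// adaptive gamma would rescale noise into signal) stay dark.
// [[Rcpp::export]]
NumericVector frangi_scale_cpp(NumericVector vol, IntegerVector dims,
                               NumericVector spacing, double sigma_um,
                               double alpha, double beta, double gamma,
                               double noise_mult) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  size_t n = (size_t)d1 * d2 * d3;
  std::vector<double> img(vol.begin(), vol.end());
  double s1 = sigma_um / spacing[0], s2 = sigma_um / spacing[1],
         s3 = sigma_um / spacing[2];
  std::vector<double> G1 = gauss_kernel(s1, K_SMOOTH), D1a = gauss_kernel(s1, K_D1),
                      D2a = gauss_kernel(s1, K_D2);
  std::vector<double> G2 = gauss_kernel(s2, K_SMOOTH), D1b = gauss_kernel(s2, K_D1),
                      D2b = gauss_kernel(s2, K_D2);
  std::vector<double> G3 = gauss_kernel(s3, K_SMOOTH), D1c = gauss_kernel(s3, K_D1),
                      D2c = gauss_kernel(s3, K_D2);
  double sn = sigma_um * sigma_um; // gamma^2-style scale normalization
  // second derivatives in physical units, scale-normalized
  std::vector<double> H11 = separable(img, d1, d2, d3, D2a, G2, G3);
  std::vector<double> H22 = separable(img, d1, d2, d3, G1, D2b, G3);
  std::vector<double> H33 = separable(img, d1, d2, d3, G1, G2, D2c);
  std::vector<double> H12 = separable(img, d1, d2, d3, D1a, D1b, G3);
  std::vector<double> H13 = separable(img, d1, d2, d3, D1a, G2, D1c);
  std::vector<double> H23 = separable(img, d1, d2, d3, G1, D1b, D1c);
  double f11 = sn / (spacing[0] * spacing[0]), f22 = sn / (spacing[1] * spacing[1]),
         f33 = sn / (spacing[2] * spacing[2]), f12 = sn / (spacing[0] * spacing[1]),
         f13 = sn / (spacing[0] * spacing[2]), f23 = sn / (spacing[1] * spacing[2]);

  std::vector<double> l1(n), l2(n), l3(n), S(n);
  double smax = 0.0;
  for (size_t i = 0; i < n; ++i) {
    double ev[3];
    sym_eig3(H11[i] * f11, H22[i] * f22, H33[i] * f33,
             H12[i] * f12, H13[i] * f13, H23[i] * f23, ev);
    // sort by absolute value
    double a = ev[0], b = ev[1], c = ev[2];
    if (std::fabs(a) > std::fabs(b)) std::swap(a, b);
    if (std::fabs(b) > std::fabs(c)) std::swap(b, c);
    if (std::fabs(a) > std::fabs(b)) std::swap(a, b);
    l1[i] = a; l2[i] = b; l3[i] = c;
    double s = std::sqrt(a * a + b * b + c * c);
    S[i] = s;
    if (s > smax) smax = s;
  }
  // an (almost) structure-free volume: do not let the adaptive gamma rescale
  // float roundoff into signal
  double vmax = 0.0;
  for (size_t i = 0; i < n; ++i)
    if (std::fabs(vol[i]) > vmax) vmax = std::fabs(vol[i]);
  if (smax <= 1e-9 * (vmax > 0.0 ? vmax : 1.0)) {
    NumericVector zero(n);
    zero.attr("dim") = dims;
    return zero;
  }
  double c2 = (gamma > 0.0) ? gamma : 0.5 * smax;
  if (noise_mult > 0.0 && n > 0) {
    std::vector<double> tmp(S);
    size_t mid = tmp.size() / 2;
    std::nth_element(tmp.begin(), tmp.begin() + mid, tmp.end());
    double medS = tmp[mid];
    for (size_t i = 0; i < tmp.size(); ++i) tmp[i] = std::fabs(S[i] - medS);
    std::nth_element(tmp.begin(), tmp.begin() + mid, tmp.end());
    double madS = tmp[mid];
    double floor_c2 = noise_mult * (madS > 0.0 ? madS : medS);
    if (floor_c2 > c2) c2 = floor_c2;
  }
  if (c2 <= 0.0) c2 = 1.0;
  NumericVector out(n);
  double a2 = 2.0 * alpha * alpha, b2 = 2.0 * beta * beta, g2 = 2.0 * c2 * c2;
  for (size_t i = 0; i < n; ++i) {
    if (l2[i] >= 0.0 || l3[i] >= 0.0) { out[i] = 0.0; continue; }
    double Ra = std::fabs(l2[i]) / std::fabs(l3[i]);
    double Rb = std::fabs(l1[i]) / std::sqrt(std::fabs(l2[i] * l3[i]));
    out[i] = (1.0 - std::exp(-Ra * Ra / a2)) * std::exp(-Rb * Rb / b2) *
             (1.0 - std::exp(-S[i] * S[i] / g2));
  }
  out.attr("dim") = dims;
  return out;
}
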