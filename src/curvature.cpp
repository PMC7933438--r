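// Per-vertex mean curvature by local quadric fitting: for each vertex a
// second-order height field z = ax^2 + bxy + cy^2 + dx + ey + f is fitted by
// least squares to the k-ring neighbourhood expressed in the local tangent
// frame (z along the area-weighted outward vertex normal); the signed mean
// curvature is -(a + c), positive where the enclosed solid is convex.
// Robust on irregular isosurface triangulations where one-ring discrete
// operators are noise-dominated.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static bool solve6(double A[6][6], double b[6], double x[6]) {
  int idx[6] = {0, 1, 2, 3, 4, 5};
  for (int c = 0; c < 6; ++c) {
    int piv = c;
    for (int r = c + 1; r < 6; ++r)
      if (std::fabs(A[idx[r]][c]) > std::fabs(A[idx[piv]][c])) piv = r;
    std::swap(idx[c], idx[piv]);
    double p = A[idx[c]][c];
    if (std::fabs(p) < 1e-14) return false;
    for (int r = c + 1; r < 6; ++r) {
      double f = A[idx[r]][c] / p;
      for (int cc = c; cc < 6; ++cc) A[idx[r]][cc] -= f * A[idx[c]][cc];
      b[idx[r]] -= f * b[idx[c]];
    }
  }
  for (int c = 5; c >= 0; --c) {
    double s = b[idx[c]];
    for (int cc = c + 1; cc < 6; ++cc) s -= A[idx[c]][cc] * x[cc];
    x[c] = s / A[idx[c]][c];
  }
  return true;
}

// [[Rcpp::export]]
NumericVector quadric_curvature_cpp(NumericMatrix V, IntegerMatrix F,
                                    int rings) {
  int nV = V.nrow(), nF = F.nrow();
  // adjacency
  std::vector<std::vector<int>> adj(nV);
  for (int f = 0; f < nF; ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    adj[a].push_back(b); adj[a].push_back(c);
    adj[b].push_back(a); adj[b].push_back(c);
    adj[c].push_back(a); adj[c].push_back(b);
  }
  for (int v = 0; v < nV; ++v) {
    std::sort(adj[v].begin(), adj[v].end());
    adj[v].erase(std::unique(adj[v].begin(), adj[v].end()), adj[v].end());
  }
  // area-weighted outward vertex normals (faces oriented outward)
  std::vector<double> nx(nV, 0), ny(nV, 0), nz(nV, 0);
  for (int f = 0; f < nF; ++f) {
    int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    double uz = V(b, 0) - V(a, 0), uy = V(b, 1) - V(a, 1), ux = V(b, 2) - V(a, 2);
    double wz = V(c, 0) - V(a, 0), wy = V(c, 1) - V(a, 1), wx = V(c, 2) - V(a, 2);
    // cross in (z,y,x) component order consistent with mesh orientation
    double cz = uy * wx - ux * wy;
    double cy = ux * wz - uz * wx;
    double cx = uz * wy - uy * wz;
    for (int s = 0; s < 3; ++s) {
      int v = F(f, s) - 1;
      nz[v] += cz; ny[v] += cy; nx[v] += cx;
    }
  }
  NumericVector H(nV);
  std::vector<int> nbr, next, cur;
  std::vector<signed char> mark(nV, 0);
  for (int v = 0; v < nV; ++v) {
    double nn = std::sqrt(nz[v] * nz[v] + ny[v] * ny[v] + nx[v] * nx[v]);
    double n0 = nz[v] / nn, n1 = ny[v] / nn, n2 = nx[v] / nn;
    // tangent frame
    double t0, t1, t2;
    if (std::fabs(n0) < 0.9) { t0 = 1; t1 = 0; t2 = 0; }
    else { t0 = 0; t1 = 1; t2 = 0; }
    double d = t0 * n0 + t1 * n1 + t2 * n2;
    t0 -= d * n0; t1 -= d * n1; t2 -= d * n2;
    double tn = std::sqrt(t0 * t0 + t1 * t1 + t2 * t2);
    t0 /= tn; t1 /= tn; t2 /= tn;
    double s0 = n1 * t2 - n2 * t1, s1 = n2 * t0 - n0 * t2,
           s2 = n0 * t1 - n1 * t0;
    // collect k-ring
    nbr.clear(); cur.clear();
    cur.push_back(v); mark[v] = 1; nbr.push_back(v);
    for (int r = 0; r < rings; ++r) {
      next.clear();
      for (int u : cur)
        for (int w : adj[u])
          if (!mark[w]) { mark[w] = 1; next.push_back(w); nbr.push_back(w); }
      cur = next;
    }
    double A[6][6] = {{0}}, bb[6] = {0};
    for (int u : nbr) {
      double pz = V(u, 0) - V(v, 0), py = V(u, 1) - V(v, 1),
             px = V(u, 2) - V(v, 2);
      double x = pz * t0 + py * t1 + px * t2;
      double y = pz * s0 + py * s1 + px * s2;
      double z = pz * n0 + py * n1 + px * n2;
      double row[6] = {x * x, x * y, y * y, x, y, 1.0};
      for (int i = 0; i < 6; ++i) {
        for (int j = 0; j < 6; ++j) A[i][j] += row[i] * row[j];
        bb[i] += row[i] * z;
      }
    }
    for (int u : nbr) mark[u] = 0;
    double coef[6];
    if ((int)nbr.size() >= 6 && solve6(A, bb, coef)) {
      // z = a x^2 + b xy + c y^2 + ... ; with z along the outward normal a
      // convex solid bends away from the normal, so H = -(a + c)
      H[v] = -(coef[0] + coef[2]);
    } else {
      H[v] = NA_REAL;
    }
  }
  return H;
}
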