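// Isosurface extraction by marching tetrahedra on the Freudenthal 6-tetrahedron
// decomposition of each grid cube. The decomposition is translation-consistent
// across the grid, so the extracted surface of an interior level set is closed
// and manifold. Vertices are welded on grid edges; triangles are oriented with
// normals pointing away from the high-valued (interior) side.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct V3 { double z, y, x; };

static inline V3 sub(const V3& a, const V3& b) { return {a.z - b.z, a.y - b.y, a.x - b.x}; }
static inline V3 cross(const V3& a, const V3& b) {
  return {a.y * b.x - a.x * b.y, a.x * b.z - a.z * b.x, a.z * b.y - a.y * b.z};
}
static inline double dot(const V3& a, const V3& b) {
  return a.z * b.z + a.y * b.y + a.x * b.x;
}

// [[Rcpp::export]]
List marching_tets_cpp(NumericVector vol, IntegerVector dims,
                       NumericVector spacing, double iso) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  auto node = [&](int i, int j, int k) -> size_t {
    return i + (size_t)d1 * (j + (size_t)d2 * k);
  };
  auto pos = [&](int i, int j, int k) -> V3 {
    return {i * spacing[0], j * spacing[1], k * spacing[2]};
  };

  // 6 Freudenthal tets: paths (0,0,0) -> (1,1,1) through axis permutations
  const int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  const int axes[3][3] = {{1,0,0},{0,1,0},{0,0,1}}; // unit steps along (z,y,x)

  std::unordered_map<unsigned long long, int> vmap;
  std::vector<double> VX; // interleaved z,y,x
  std::vector<int> FF;
  size_t ntot = (size_t)d1 * d2 * d3;

  auto edge_vertex = [&](size_t ga, size_t gb, const V3& pa, const V3& pb,
                         double va, double vb) -> int {
    unsigned long long key = (ga < gb)
      ? (unsigned long long)ga * (unsigned long long)ntot + gb
      : (unsigned long long)gb * (unsigned long long)ntot + ga;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double t = (iso - va) / (vb - va);
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
    V3 p = {pa.z + t * (pb.z - pa.z), pa.y + t * (pb.y - pa.y),
            pa.x + t * (pb.x - pa.x)};
    int id = (int)(VX.size() / 3);
    VX.push_back(p.z); VX.push_back(p.y); VX.push_back(p.x);
    vmap.emplace(key, id);
    return id;
  };

  auto add_tri = [&](int a, int b, int c, const V3& inside_pos) {
    V3 p0 = {VX[3*a], VX[3*a+1], VX[3*a+2]};
    V3 p1 = {VX[3*b], VX[3*b+1], VX[3*b+2]};
    V3 p2 = {VX[3*c], VX[3*c+1], VX[3*c+2]};
    V3 nrm = cross(sub(p1, p0), sub(p2, p0));
    V3 cen = {(p0.z + p1.z + p2.z) / 3.0, (p0.y + p1.y + p2.y) / 3.0,
              (p0.x + p1.x + p2.x) / 3.0};
    if (dot(nrm, sub(cen, inside_pos)) < 0.0) std::swap(b, c);
    FF.push_back(a); FF.push_back(b); FF.push_back(c);
  };

  for (int k = 0; k < d3 - 1; ++k)
    for (int j = 0; j < d2 - 1; ++j)
      for (int i = 0; i < d1 - 1; ++i) {
        // skip cubes entirely inside or outside
        double vmin = 1e300, vmax = -1e300;
        for (int dz = 0; dz <= 1; ++dz)
          for (int dy = 0; dy <= 1; ++dy)
            for (int dx = 0; dx <= 1; ++dx) {
              double v = vol[node(i + dz, j + dy, k + dx)];
              if (v < vmin) vmin = v;
              if (v > vmax) vmax = v;
            }
        if (vmin > iso || vmax <= iso) continue;
        for (int t = 0; t < 6; ++t) {
          int ci[4][3];
          ci[0][0] = i; ci[0][1] = j; ci[0][2] = k;
          for (int s = 1; s < 4; ++s) {
            const int* step = axes[perms[t][s - 1]];
            ci[s][0] = ci[s - 1][0] + step[0];
            ci[s][1] = ci[s - 1][1] + step[1];
            ci[s][2] = ci[s - 1][2] + step[2];
          }
          double val[4];
          size_t gid[4];
          V3 pp[4];
          int code = 0;
          for (int s = 0; s < 4; ++s) {
            gid[s] = node(ci[s][0], ci[s][1], ci[s][2]);
            val[s] = vol[gid[s]];
            pp[s] = pos(ci[s][0], ci[s][1], ci[s][2]);
            if (val[s] > iso) code |= (1 << s);
          }
          if (code == 0 || code == 15) continue;
          int ins[4], outs[4], ni = 0, no = 0;
          for (int s = 0; s < 4; ++s) {
            if (code & (1 << s)) ins[ni++] = s; else outs[no++] = s;
          }
          auto ev = [&](int a, int b) {
            return edge_vertex(gid[a], gid[b], pp[a], pp[b], val[a], val[b]);
          };
          if (ni == 1) {
            int A = ins[0];
            add_tri(ev(A, outs[0]), ev(A, outs[1]), ev(A, outs[2]), pp[A]);
          } else if (ni == 3) {
            int A = outs[0];
            add_tri(ev(A, ins[0]), ev(A, ins[1]), ev(A, ins[2]), pp[ins[0]]);
          } else {
            int A = ins[0], B = ins[1], C = outs[0], D = outs[1];
            int vAC = ev(A, C), vAD = ev(A, D), vBD = ev(B, D), vBC = ev(B, C);
            add_tri(vAC, vAD, vBD, pp[A]);
            add_tri(vAC, vBD, vBC, pp[A]);
          }
        }
      }

  int nV = (int)(VX.size() / 3), nF = (int)(FF.size() / 3);
  NumericMatrix V(nV, 3);
  for (int v = 0; v < nV; ++v) {
    V(v, 0) = VX[3 * v];
    V(v, 1) = VX[3 * v + 1];
    V(v, 2) = VX[3 * v + 2];
  }
  IntegerMatrix F(nF, 3);
  for (int f = 0; f < nF; ++f) {
    F(f, 0) = FF[3 * f] + 1;
    F(f, 1) = FF[3 * f + 1] + 1;
    F(f, 2) = FF[3 * f + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
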