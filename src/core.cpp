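#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Iso-surface extraction on the tetrahedral (Freudenthal) decomposition of the
// voxel grid.  Every cube of 8 neighbouring voxel centres is split into the
// same 6 tetrahedra around its main diagonal; the split is face-consistent
// between neighbouring cubes, so linearly interpolated crossings on shared
// edges coincide and the resulting surface is watertight and edge-manifold.
// Vertices on grid edges are welded through a hash on the (node, node) pair.
// ---------------------------------------------------------------------------

struct MTBuilder {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;   // physical mm (x = axis3, y = axis2, z = axis1)
  std::vector<int> tri;             // 0-based vertex indices, 3 per face
};

static inline uint64_t edge_key(int64_t a, int64_t b) {
  if (a > b) std::swap(a, b);
  return (static_cast<uint64_t>(a) << 32) | static_cast<uint64_t>(b);
}

// linear interpolation of the iso crossing on grid edge (a, b)
static int crossing_vertex(MTBuilder &B, int64_t la, int64_t lb,
                           const double *pa, const double *pb,
                           double va, double vb, double iso) {
  uint64_t key = edge_key(la, lb);
  auto it = B.edge_vertex.find(key);
  if (it != B.edge_vertex.end()) return it->second;
  double t = (iso - va) / (vb - va);
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  int idx = static_cast<int>(B.vx.size());
  B.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
  B.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
  B.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
  B.edge_vertex.emplace(key, idx);
  return idx;
}

static inline void emit_tri(MTBuilder &B, int a, int b, int c,
                            const double *outward) {
  // orient so the face normal has positive dot with the outward direction
  double e1x = B.vx[b] - B.vx[a], e1y = B.vy[b] - B.vy[a], e1z = B.vz[b] - B.vz[a];
  double e2x = B.vx[c] - B.vx[a], e2y = B.vy[c] - B.vy[a], e2z = B.vz[c] - B.vz[a];
  double nx = e1y * e2z - e1z * e2y;
  double ny = e1z * e2x - e1x * e2z;
  double nz = e1x * e2y - e1y * e2x;
  double d = nx * outward[0] + ny * outward[1] + nz * outward[2];
  if (d >= 0) {
    B.tri.push_back(a); B.tri.push_back(b); B.tri.push_back(c);
  } else {
    B.tri.push_back(a); B.tri.push_back(c); B.tri.push_back(b);
  }
}

// [[Rcpp::export(name = ".mt_surface")]]
List mt_surface(NumericVector vol, double iso,
                NumericVector spacing, NumericVector origin) {
  IntegerVector dm = vol.attr("dim");
  const int n1 = dm[0], n2 = dm[1], n3 = dm[2];
  const double s1 = spacing[0], s2 = spacing[1], s3 = spacing[2];
  const double o1 = origin[0], o2 = origin[1], o3 = origin[2];
  const double *v = REAL(vol);

  // values exactly at iso are nudged inside so no crossing lands on a node
  auto val = [&](int64_t lin) {
    double x = v[lin];
    return (x == iso) ? iso + 1e-9 * (std::fabs(iso) + 1.0) : x;
  };
  auto lin_of = [&](int i, int j, int k) -> int64_t {
    return static_cast<int64_t>(i) +
           static_cast<int64_t>(n1) * (j + static_cast<int64_t>(n2) * k);
  };

  // the 6 tetrahedra: axis orders (permutations of 0,1,2) walking the cube
  static const int perms[6][3] = {
    {0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};

  MTBuilder B;
  int corner[4][3];
  int64_t lins[4];
  double pos[4][3], vals[4];

  for (int k = 0; k + 1 < n3; ++k)
    for (int j = 0; j + 1 < n2; ++j)
      for (int i = 0; i + 1 < n1; ++i) {
        // quick reject: all 8 on one side
        bool any_in = false, any_out = false;
        for (int d = 0; d < 8; ++d) {
          double x = val(lin_of(i + (d & 1), j + ((d >> 1) & 1), k + (d >> 2)));
          if (x >= iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          corner[0][0] = i; corner[0][1] = j; corner[0][2] = k;
          for (int s = 0; s < 3; ++s) {
            corner[s + 1][0] = corner[s][0];
            corner[s + 1][1] = corner[s][1];
            corner[s + 1][2] = corner[s][2];
            corner[s + 1][perms[t][s]] += 1;
          }
          int n_in = 0;
          int in_idx[4], out_idx[4];
          int n_out = 0;
          for (int s = 0; s < 4; ++s) {
            lins[s] = lin_of(corner[s][0], corner[s][1], corner[s][2]);
            vals[s] = val(lins[s]);
            // physical position: x from axis3, y from axis2, z from axis1
            pos[s][0] = o3 + corner[s][2] * s3;
            pos[s][1] = o2 + corner[s][1] * s2;
            pos[s][2] = o1 + corner[s][0] * s1;
            if (vals[s] >= iso) in_idx[n_in++] = s; else out_idx[n_out++] = s;
          }
          if (n_in == 0 || n_in == 4) continue;

          if (n_in == 1 || n_in == 3) {
            int apex = (n_in == 1) ? in_idx[0] : out_idx[0];
            int others[3], m = 0;
            for (int s = 0; s < 4; ++s) if (s != apex) others[m++] = s;
            int p0 = crossing_vertex(B, lins[apex], lins[others[0]],
                                     pos[apex], pos[others[0]],
                                     vals[apex], vals[others[0]], iso);
            int p1 = crossing_vertex(B, lins[apex], lins[others[1]],
                                     pos[apex], pos[others[1]],
                                     vals[apex], vals[others[1]], iso);
            int p2 = crossing_vertex(B, lins[apex], lins[others[2]],
                                     pos[apex], pos[others[2]],
                                     vals[apex], vals[others[2]], iso);
            double cx = (B.vx[p0] + B.vx[p1] + B.vx[p2]) / 3.0;
            double cy = (B.vy[p0] + B.vy[p1] + B.vy[p2]) / 3.0;
            double cz = (B.vz[p0] + B.vz[p1] + B.vz[p2]) / 3.0;
            double outward[3];
            if (n_in == 1) {          // away from the single inside vertex
              outward[0] = cx - pos[apex][0];
              outward[1] = cy - pos[apex][1];
              outward[2] = cz - pos[apex][2];
            } else {                  // toward the single outside vertex
              outward[0] = pos[apex][0] - cx;
              outward[1] = pos[apex][1] - cy;
              outward[2] = pos[apex][2] - cz;
            }
            emit_tri(B, p0, p1, p2, outward);
          } else {                    // 2 in, 2 out: quad split in two
            int A = in_idx[0], Bv = in_idx[1], C = out_idx[0], D = out_idx[1];
            int pAC = crossing_vertex(B, lins[A], lins[C], pos[A], pos[C],
                                      vals[A], vals[C], iso);
            int pAD = crossing_vertex(B, lins[A], lins[D], pos[A], pos[D],
                                      vals[A], vals[D], iso);
            int pBC = crossing_vertex(B, lins[Bv], lins[C], pos[Bv], pos[C],
                                      vals[Bv], vals[C], iso);
            int pBD = crossing_vertex(B, lins[Bv], lins[D], pos[Bv], pos[D],
                                      vals[Bv], vals[D], iso);
            double outward[3] = {
              (pos[C][0] + pos[D][0] - pos[A][0] - pos[Bv][0]) / 2.0,
              (pos[C][1] + pos[D][1] - pos[A][1] - pos[Bv][1]) / 2.0,
              (pos[C][2] + pos[D][2] - pos[A][2] - pos[Bv][2]) / 2.0};
            emit_tri(B, pAC, pAD, pBD, outward);
            emit_tri(B, pAC, pBD, pBC, outward);
          }
        }
      }

  const int nv = static_cast<int>(B.vx.size());
  const int nf = static_cast<int>(B.tri.size() / 3);
  NumericMatrix verts(nv, 3);
  for (int a = 0; a < nv; ++a) {
    verts(a, 0) = B.vx[a]; verts(a, 1) = B.vy[a]; verts(a, 2) = B.vz[a];
  }
  IntegerMatrix faces(nf, 3);
  for (int f = 0; f < nf; ++f) {
    faces(f, 0) = B.tri[3 * f] + 1;
    faces(f, 1) = B.tri[3 * f + 1] + 1;
    faces(f, 2) = B.tri[3 * f + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}

// ---------------------------------------------------------------------------
// Connected-component labelling of nonzero voxels (6- or 26-connectivity).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(IntegerVector mask, int connectivity) {
  IntegerVector dm = mask.attr("dim");
  const int n1 = dm[0], n2 = dm[1], n3 = dm[2];
  const int64_t n = static_cast<int64_t>(n1) * n2 * n3;
  const int *m = INTEGER(mask);
  IntegerVector labels(n, 0);
  labels.attr("dim") = dm;
  int *lab = INTEGER(labels);

  std::vector<int64_t> stack;
  int next_label = 0;
  for (int64_t start = 0; start < n; ++start) {
    if (m[start] == 0 || lab[start] != 0) continue;
    ++next_label;
    lab[start] = next_label;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      int64_t cur = stack.back(); stack.pop_back();
      int i = static_cast<int>(cur % n1);
      int j = static_cast<int>((cur / n1) % n2);
      int k = static_cast<int>(cur / (static_cast<int64_t>(n1) * n2));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            if (connectivity == 6 &&
                std::abs(di) + std::abs(dj) + std::abs(dk) != 1) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 ||
                kk < 0 || kk >= n3) continue;
            int64_t nb = ii + static_cast<int64_t>(n1) * (jj + static_cast<int64_t>(n2) * kk);
            if (m[nb] != 0 && lab[nb] == 0) {
              lab[nb] = next_label;
              stack.push_back(nb);
            }
          }
    }
  }
  return labels;
}

// ---------------------------------------------------------------------------
// Exact Euclidean squared distance transform (Felzenszwalb & Huttenlocher),
// generalised to anisotropic sample spacing: distance to the nearest nonzero
// voxel, in physical units.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double w) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * w;
    double s;
    while (true) {
      double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * w;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(IntegerVector feature, NumericVector spacing) {
  IntegerVector dm = feature.attr("dim");
  const int n1 = dm[0], n2 = dm[1], n3 = dm[2];
  const int64_t n = static_cast<int64_t>(n1) * n2 * n3;
  // large finite stand-in for "no feature": keeps the parabola
  // intersections finite (infinities would produce NaN differences)
  const double FAR = 1e20;
  NumericVector out(n);
  out.attr("dim") = dm;
  double *D = REAL(out);
  const int *ft = INTEGER(feature);
  for (int64_t p = 0; p < n; ++p) D[p] = ft[p] != 0 ? 0.0 : FAR;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      int64_t base = static_cast<int64_t>(n1) * (j + static_cast<int64_t>(n2) * k);
      for (int i = 0; i < n1; ++i) f[i] = D[base + i];
      dt1d(f, d, v, z, n1, spacing[0]);
      for (int i = 0; i < n1; ++i) D[base + i] = d[i];
    }
  // axis 2
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      int64_t base = i + static_cast<int64_t>(n1) * n2 * static_cast<int64_t>(k);
      for (int j = 0; j < n2; ++j) f[j] = D[base + static_cast<int64_t>(n1) * j];
      dt1d(f, d, v, z, n2, spacing[1]);
      for (int j = 0; j < n2; ++j) D[base + static_cast<int64_t>(n1) * j] = d[j];
    }
  // axis 3
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      int64_t base = i + static_cast<int64_t>(n1) * j;
      int64_t stride = static_cast<int64_t>(n1) * n2;
      for (int k = 0; k < n3; ++k) f[k] = D[base + stride * k];
      dt1d(f, d, v, z, n3, spacing[2]);
      for (int k = 0; k < n3; ++k) D[base + stride * k] = d[k];
    }
  return out;
}

// ---------------------------------------------------------------------------
// Separable 1D convolution along one array axis with replicate borders.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".conv1d_axis")]]
NumericVector conv1d_axis(NumericVector vol, NumericVector kernel, int axis) {
  IntegerVector dm = vol.attr("dim");
  const int n1 = dm[0], n2 = dm[1], n3 = dm[2];
  const int64_t n = static_cast<int64_t>(n1) * n2 * n3;
  const double *v = REAL(vol);
  NumericVector out(n);
  out.attr("dim") = dm;
  double *o = REAL(out);
  const int klen = kernel.size();
  const int r = klen / 2;
  const double *kv = REAL(kernel);

  int len;
  int64_t stride;
  if (axis == 1) { len = n1; stride = 1; }
  else if (axis == 2) { len = n2; stride = n1; }
  else { len = n3; stride = static_cast<int64_t>(n1) * n2; }

  // iterate over all lines along `axis`
  for (int64_t p = 0; p < n; ++p) {
    int idx_along;
    if (axis == 1) idx_along = static_cast<int>(p % n1);
    else if (axis == 2) idx_along = static_cast<int>((p / n1) % n2);
    else idx_along = static_cast<int>(p / (static_cast<int64_t>(n1) * n2));
    double acc = 0.0;
    int64_t line0 = p - static_cast<int64_t>(idx_along) * stride;
    for (int t = 0; t < klen; ++t) {
      int q = idx_along + t - r;
      if (q < 0) q = 0;
      if (q >= len) q = len - 1;
      acc += kv[t] * v[line0 + static_cast<int64_t>(q) * stride];
    }
    o[p] = acc;
  }
  return out;
}
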