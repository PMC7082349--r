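#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// levels: 3D integer array, 0 outside the ROI, 1..ng inside.

static inline int idx3(int i, int j, int k, int n1, int n2) {
  return i + n1 * (j + n2 * k);
}

// Pair counts along each offset (unsymmetrized, one pass per direction).
// [[Rcpp::export(name = ".glcm_counts")]]
IntegerVector glcm_counts(IntegerVector levels, IntegerVector dims, int ng,
                          IntegerMatrix offsets) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2], nd = offsets.nrow();
  IntegerVector out(ng * ng * nd);
  for (int d = 0; d < nd; ++d) {
    int dx = offsets(d, 0), dy = offsets(d, 1), dz = offsets(d, 2);
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          int li = levels[idx3(i, j, k, n1, n2)];
          if (li == 0) continue;
          int i2 = i + dx, j2 = j + dy, k2 = k + dz;
          if (i2 < 0 || i2 >= n1 || j2 < 0 || j2 >= n2 || k2 < 0 || k2 >= n3)
            continue;
          int lj = levels[idx3(i2, j2, k2, n1, n2)];
          if (lj == 0) continue;
          out[(li - 1) + ng * ((lj - 1) + ng * d)]++;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, nd);
  return out;
}

// Maximal same-level runs per direction: counts[level, length, direction].
// [[Rcpp::export(name = ".glrlm_counts")]]
IntegerVector glrlm_counts(IntegerVector levels, IntegerVector dims, int ng,
                           IntegerMatrix offsets, int max_len) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2], nd = offsets.nrow();
  IntegerVector out(ng * max_len * nd);
  for (int d = 0; d < nd; ++d) {
    int dx = offsets(d, 0), dy = offsets(d, 1), dz = offsets(d, 2);
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          int l = levels[idx3(i, j, k, n1, n2)];
          if (l == 0) continue;
          int ip = i - dx, jp = j - dy, kp = k - dz;
          // run starts here unless the previous voxel continues it
          if (ip >= 0 && ip < n1 && jp >= 0 && jp < n2 && kp >= 0 && kp < n3 &&
              levels[idx3(ip, jp, kp, n1, n2)] == l)
            continue;
          int len = 1, ic = i + dx, jc = j + dy, kc = k + dz;
          while (ic >= 0 && ic < n1 && jc >= 0 && jc < n2 && kc >= 0 &&
                 kc < n3 && levels[idx3(ic, jc, kc, n1, n2)] == l) {
            ++len; ic += dx; jc += dy; kc += dz;
          }
          if (len > max_len) len = max_len; // cannot occur with max_len = max(dims)
          out[(l - 1) + ng * ((len - 1) + max_len * d)]++;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, max_len, nd);
  return out;
}

// Connected zones of equal level (26-connectivity); rows = (level, size).
// [[Rcpp::export(name = ".glszm_zones")]]
IntegerMatrix glszm_zones(IntegerVector levels, IntegerVector dims) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  std::vector<char> seen((size_t)n1 * n2 * n3, 0);
  std::vector<std::pair<int, int> > zones;
  std::vector<int> stack;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int p = idx3(i, j, k, n1, n2);
        int l = levels[p];
        if (l == 0 || seen[p]) continue;
        int size = 0;
        stack.clear();
        stack.push_back(p);
        seen[p] = 1;
        while (!stack.empty()) {
          int q = stack.back(); stack.pop_back();
          ++size;
          int qi = q % n1, qj = (q / n1) % n2, qk = q / (n1 * n2);
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dx && !dy && !dz) continue;
                int ii = qi + dx, jj = qj + dy, kk = qk + dz;
                if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 ||
                    kk >= n3)
                  continue;
                int r = idx3(ii, jj, kk, n1, n2);
                if (!seen[r] && levels[r] == l) {
                  seen[r] = 1;
                  stack.push_back(r);
                }
              }
        }
        zones.push_back(std::make_pair(l, size));
      }
  IntegerMatrix out(zones.size(), 2);
  for (size_t z = 0; z < zones.size(); ++z) {
    out(z, 0) = zones[z].first;
    out(z, 1) = zones[z].second;
  }
  return out;
}

// NGTDM: per level, count of valid voxels n_i and summed |gray - nbhd mean|
// s_i over the 26-neighborhood restricted to the ROI.
// [[Rcpp::export(name = ".ngtdm_counts")]]
List ngtdm_counts(IntegerVector levels, IntegerVector dims, int ng) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  IntegerVector ncount(ng);
  NumericVector s(ng);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int l = levels[idx3(i, j, k, n1, n2)];
        if (l == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int ii = i + dx, jj = j + dy, kk = k + dz;
              if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 ||
                  kk >= n3)
                continue;
              int ln = levels[idx3(ii, jj, kk, n1, n2)];
              if (ln > 0) { sum += ln; ++cnt; }
            }
        if (cnt == 0) continue; // isolated voxel: no valid neighborhood
        ncount[l - 1]++;
        s[l - 1] += std::fabs((double)l - sum / cnt);
      }
  return List::create(_["n"] = ncount, _["s"] = s);
}

// ---- marching tetrahedra surface area ------------------------------------

static const int TET[6][4] = {
  // six tetrahedra sharing the main diagonal 0-7 of the unit cube;
  // corner c has offsets (c&1, c>>1&1, c>>2&1)
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
};

static inline void add_tri(const double *a, const double *b, const double *c,
                           const double *inside, double &area, double &vol) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double n[3] = {u[1] * v[2] - u[2] * v[1], u[2] * v[0] - u[0] * v[2],
                 u[0] * v[1] - u[1] * v[0]};
  area += 0.5 * std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
  // orient outward (away from the inside reference point), then apply the
  // divergence theorem: V = sum dot(a, b x c) / 6 over outward triangles
  double w[3] = {a[0] - inside[0], a[1] - inside[1], a[2] - inside[2]};
  double sign = (n[0] * w[0] + n[1] * w[1] + n[2] * w[2]) >= 0 ? 1.0 : -1.0;
  double bxc[3] = {b[1] * c[2] - b[2] * c[1], b[2] * c[0] - b[0] * c[2],
                   b[0] * c[1] - b[1] * c[0]};
  vol += sign * (a[0] * bxc[0] + a[1] * bxc[1] + a[2] * bxc[2]) / 6.0;
}

// Surface area (mm^2) and enclosed volume (mm^3) of the `iso` level set of
// a scalar field, triangulated by marching tetrahedra with linear
// interpolation of the edge crossings. Out-of-range samples are treated as
// 0 so the surface closes at the array border.
// [[Rcpp::export(name = ".mt_surface_mesh")]]
NumericVector mt_surface_mesh(NumericVector field, IntegerVector dims,
                              NumericVector spacing, double iso) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  double area = 0.0, vol = 0.0;
  for (int k = -1; k < n3; ++k)
    for (int j = -1; j < n2; ++j)
      for (int i = -1; i < n1; ++i) {
        double val[8];
        int any1 = 0, all1 = 1;
        double crd[8][3];
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          double v = 0.0;
          if (ci >= 0 && ci < n1 && cj >= 0 && cj < n2 && ck >= 0 && ck < n3)
            v = field[idx3(ci, cj, ck, n1, n2)];
          val[c] = v;
          if (v > iso) any1 = 1; else all1 = 0;
          crd[c][0] = ci * sx; crd[c][1] = cj * sy; crd[c][2] = ck * sz;
        }
        if (!any1 || all1) continue;
        for (int t = 0; t < 6; ++t) {
          int in[4], nin = 0, out[4], nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (val[TET[t][c]] > iso) in[nin++] = TET[t][c];
            else out[nout++] = TET[t][c];
          }
          if (nin == 0 || nin == 4) continue;
          double m[4][3], ref[3];
          // crossing of the edge a(inside) - b(outside)
          #define CROSS(dst, a, b)                                        \
            { double tt = (iso - val[a]) / (val[b] - val[a]);             \
              for (int x = 0; x < 3; ++x)                                 \
                dst[x] = crd[a][x] + tt * (crd[b][x] - crd[a][x]); }
          for (int x = 0; x < 3; ++x) {
            ref[x] = 0.0;
            for (int c = 0; c < nin; ++c) ref[x] += crd[in[c]][x];
            ref[x] /= nin;
          }
          if (nin == 1) {
            for (int e = 0; e < 3; ++e) CROSS(m[e], in[0], out[e]);
            add_tri(m[0], m[1], m[2], ref, area, vol);
          } else if (nin == 3) {
            for (int e = 0; e < 3; ++e) CROSS(m[e], in[e], out[0]);
            add_tri(m[0], m[1], m[2], ref, area, vol);
          } else { // 2 in, 2 out: quad m(a,c) m(a,d) m(b,d) m(b,c)
            CROSS(m[0], in[0], out[0]);
            CROSS(m[1], in[0], out[1]);
            CROSS(m[2], in[1], out[1]);
            CROSS(m[3], in[1], out[0]);
            add_tri(m[0], m[1], m[2], ref, area, vol);
            add_tri(m[0], m[2], m[3], ref, area, vol);
          }
          #undef CROSS
        }
      }
  return NumericVector::create(area, vol);
}

// Largest pairwise Euclidean distance between rows of a coordinate matrix.
// [[Rcpp::export(name = ".max_pairwise_dist")]]
double max_pairwise_dist(NumericMatrix coords) {
  int n = coords.nrow();
  double best = 0.0;
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      double dx = coords(a, 0) - coords(b, 0);
      double dy = coords(a, 1) - coords(b, 1);
      double dz = coords(a, 2) - coords(b, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}
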