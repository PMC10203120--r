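// Low-level morphological primitives shared by the 2D and 3D pipelines.
// All arrays are R column-major with dims (y, x) or (y, x, z); a 2D input
// is treated as a 3D array with a singleton z. Connectivity codes: 4/8
// in-plane, 6/18/26 volumetric. Every routine is deterministic: ties are
// broken by insertion order (FIFO) or by linear (column-major) index.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <array>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double BIG = 1e30;

// ---------------------------------------------------------------------------
// 1-D squared distance transform (lower envelope of parabolas) on a grid
// with step `s`. f holds squared distances on input, overwritten on output.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n, double s) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double qs = q * s;
    double sq = f[q] + qs * qs;
    while (true) {
      double vs = v[k] * s;
      double inter = (sq - (f[v[k]] + vs * vs)) / (2.0 * qs - 2.0 * vs);
      if (inter <= z[k]) {
        k--;
      } else {
        k++;
        v[k] = q;
        z[k] = inter;
        z[k + 1] = BIG;
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double qs = q * s;
    while (z[k + 1] < qs) k++;
    double diff = qs - v[k] * s;
    d[q] = diff * diff + f[v[k]];
  }
}

struct Dims3 {
  int d1, d2, d3;     // y, x, z
  R_xlen_t n;
  Dims3(IntegerVector dims) {
    d1 = dims[0];
    d2 = dims.size() > 1 ? dims[1] : 1;
    d3 = dims.size() > 2 ? dims[2] : 1;
    n = (R_xlen_t)d1 * d2 * d3;
  }
};

// Euclidean distance transform: distance from each foreground (nonzero)
// element to the nearest background (zero) element, with per-axis spacing.
// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(IntegerVector fg, IntegerVector dims,
                      NumericVector spacing) {
  Dims3 D(dims);
  NumericVector out(D.n);
  for (R_xlen_t i = 0; i < D.n; i++) out[i] = fg[i] ? BIG : 0.0;

  int dsz[3] = {D.d1, D.d2, D.d3};
  R_xlen_t stride[3] = {1, (R_xlen_t)D.d1, (R_xlen_t)D.d1 * D.d2};
  double sp[3] = {spacing[0],
                  spacing.size() > 1 ? spacing[1] : spacing[0],
                  spacing.size() > 2 ? spacing[2] : spacing[0]};

  int maxd = std::max(std::max(D.d1, D.d2), D.d3);
  std::vector<double> f(maxd), d(maxd), z(maxd + 1);
  std::vector<int> v(maxd);

  for (int ax = 0; ax < 3; ax++) {
    int len = dsz[ax];
    if (len <= 1) continue;
    R_xlen_t nlines = D.n / len;
    for (R_xlen_t line = 0; line < nlines; line++) {
      // decompose `line` into coordinates of the other two axes
      R_xlen_t rem = line, base = 0;
      for (int a2 = 0; a2 < 3; a2++) {
        if (a2 == ax) continue;
        R_xlen_t c = rem % dsz[a2];
        rem /= dsz[a2];
        base += c * stride[a2];
      }
      for (int i = 0; i < len; i++) f[i] = out[base + i * stride[ax]];
      dt1d(f, d, v, z, len, sp[ax]);
      for (int i = 0; i < len; i++) out[base + i * stride[ax]] = d[i];
    }
  }
  for (R_xlen_t i = 0; i < D.n; i++) out[i] = std::sqrt(out[i]);
  IntegerVector dm(dims.size());
  for (int i = 0; i < dims.size(); i++) dm[i] = dims[i];
  out.attr("dim") = dm;
  return out;
}

// Separable Gaussian smoothing, kernel truncated at 4 sigma, edge-replicate
// boundary handling. sigma is in pixels, applied along y and x only when
// `inplane` is true (the slice-wise pipeline), along all axes otherwise.
// [[Rcpp::export(name = ".gauss_cpp")]]
NumericVector gauss_cpp(NumericVector x, IntegerVector dims, double sigma,
                        bool inplane) {
  Dims3 D(dims);
  NumericVector out = clone(x);
  if (sigma <= 0) {
    out.attr("dim") = x.attr("dim");
    return out;
  }
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; i++) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &w : k) w /= s;

  int dsz[3] = {D.d1, D.d2, D.d3};
  R_xlen_t stride[3] = {1, (R_xlen_t)D.d1, (R_xlen_t)D.d1 * D.d2};
  int naxes = inplane ? 2 : 3;
  std::vector<double> buf(std::max(std::max(D.d1, D.d2), D.d3));

  for (int ax = 0; ax < naxes; ax++) {
    int len = dsz[ax];
    if (len <= 1) continue;
    R_xlen_t nlines = D.n / len;
    for (R_xlen_t line = 0; line < nlines; line++) {
      R_xlen_t rem = line, base = 0;
      for (int a2 = 0; a2 < 3; a2++) {
        if (a2 == ax) continue;
        R_xlen_t c = rem % dsz[a2];
        rem /= dsz[a2];
        base += c * stride[a2];
      }
      for (int i = 0; i < len; i++) buf[i] = out[base + i * stride[ax]];
      for (int i = 0; i < len; i++) {
        double acc = 0;
        for (int j = -r; j <= r; j++) {
          int p = i + j;
          if (p < 0) p = 0;
          if (p >= len) p = len - 1;
          acc += k[j + r] * buf[p];
        }
        out[base + i * stride[ax]] = acc;
      }
    }
  }
  out.attr("dim") = x.attr("dim");
  return out;
}

// Neighbour offsets for a connectivity code, as (dy, dx, dz) triples.
static std::vector<std::array<int, 3>> neigh_offsets(int conn, bool is3d) {
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; dz++) {
    if (!is3d && dz != 0) continue;
    for (int dx = -1; dx <= 1; dx++) {
      for (int dy = -1; dy <= 1; dy++) {
        if (dy == 0 && dx == 0 && dz == 0) continue;
        int man = std::abs(dy) + std::abs(dx) + std::abs(dz);
        bool keep;
        if (!is3d) {
          keep = (conn == 8) || man == 1;
        } else {
          if (conn == 6) keep = man == 1;
          else if (conn == 18) keep = man <= 2;
          else keep = true; // 26
        }
        if (keep) offs.push_back({dy, dx, dz});
      }
    }
  }
  return offs;
}

// Morphological grayscale reconstruction by dilation of `marker` under
// `mask` (Vincent's hybrid raster/FIFO algorithm).
// [[Rcpp::export(name = ".reconstruct_cpp")]]
NumericVector reconstruct_cpp(NumericVector marker, NumericVector mask,
                              IntegerVector dims, int conn) {
  Dims3 D(dims);
  bool is3d = D.d3 > 1;
  NumericVector J = clone(marker);
  std::vector<std::array<int, 3>> offs = neigh_offsets(conn, is3d);
  std::vector<std::array<int, 3>> fwd, bwd;
  for (auto &o : offs) {
    R_xlen_t lin = o[0] + (R_xlen_t)o[1] * D.d1 + (R_xlen_t)o[2] * D.d1 * D.d2;
    if (lin < 0) bwd.push_back(o); else fwd.push_back(o);
  }
  R_xlen_t sxy = (R_xlen_t)D.d1 * D.d2;

  auto scan = [&](bool forward) {
    R_xlen_t i = forward ? 0 : D.n - 1;
    R_xlen_t end = forward ? D.n : -1;
    int step = forward ? 1 : -1;
    auto &nb = forward ? bwd : fwd;
    for (; i != end; i += step) {
      int y = (int)(i % D.d1);
      int x = (int)((i / D.d1) % D.d2);
      int z = (int)(i / sxy);
      double m = J[i];
      for (auto &o : nb) {
        int yy = y + o[0], xx = x + o[1], zz = z + o[2];
        if (yy < 0 || yy >= D.d1 || xx < 0 || xx >= D.d2 || zz < 0 ||
            zz >= D.d3)
          continue;
        double v = J[yy + (R_xlen_t)xx * D.d1 + (R_xlen_t)zz * sxy];
        if (v > m) m = v;
      }
      J[i] = std::min(m, mask[i]);
    }
  };
  scan(true);

  std::queue<R_xlen_t> fifo;
  {
    for (R_xlen_t i = D.n - 1; i >= 0; i--) {
      int y = (int)(i % D.d1);
      int x = (int)((i / D.d1) % D.d2);
      int z = (int)(i / sxy);
      double m = J[i];
      bool enq = false;
      for (auto &o : fwd) {
        int yy = y + o[0], xx = x + o[1], zz = z + o[2];
        if (yy < 0 || yy >= D.d1 || xx < 0 || xx >= D.d2 || zz < 0 ||
            zz >= D.d3)
          continue;
        R_xlen_t q = yy + (R_xlen_t)xx * D.d1 + (R_xlen_t)zz * sxy;
        if (J[q] > m) m = J[q];
      }
      J[i] = std::min(m, mask[i]);
      for (auto &o : fwd) {
        int yy = y + o[0], xx = x + o[1], zz = z + o[2];
        if (yy < 0 || yy >= D.d1 || xx < 0 || xx >= D.d2 || zz < 0 ||
            zz >= D.d3)
          continue;
        R_xlen_t q = yy + (R_xlen_t)xx * D.d1 + (R_xlen_t)zz * sxy;
        if (J[q] < J[i] && J[q] < mask[q]) enq = true;
      }
      if (enq) fifo.push(i);
    }
  }
  std::vector<std::array<int, 3>> all = offs;
  while (!fifo.empty()) {
    R_xlen_t p = fifo.front();
    fifo.pop();
    int y = (int)(p % D.d1);
    int x = (int)((p / D.d1) % D.d2);
    int z = (int)(p / sxy);
    for (auto &o : all) {
      int yy = y + o[0], xx = x + o[1], zz = z + o[2];
      if (yy < 0 || yy >= D.d1 || xx < 0 || xx >= D.d2 || zz < 0 ||
          zz >= D.d3)
        continue;
      R_xlen_t q = yy + (R_xlen_t)xx * D.d1 + (R_xlen_t)zz * sxy;
      if (J[q] < J[p] && mask[q] != J[q]) {
        J[q] = std::min(J[p], mask[q]);
        fifo.push(q);
      }
    }
  }
  J.attr("dim") = marker.attr("dim");
  return J;
}

// Connected-component labelling of a binary array. Components are numbered
// 1..k in the order their first (lowest linear index) element is met.
// [[Rcpp::export(name = ".label_cpp")]]
IntegerVector label_cpp(IntegerVector mask, IntegerVector dims, int conn) {
  Dims3 D(dims);
  bool is3d = D.d3 > 1;
  std::vector<std::array<int, 3>> offs = neigh_offsets(conn, is3d);
  IntegerVector out(D.n);
  R_xlen_t sxy = (R_xlen_t)D.d1 * D.d2;
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < D.n; i++) {
    if (!mask[i] || out[i]) continue;
    next++;
    out[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int y = (int)(p % D.d1);
      int x = (int)((p / D.d1) % D.d2);
      int z = (int)(p / sxy);
      for (auto &o : offs) {
        int yy = y + o[0], xx = x + o[1], zz = z + o[2];
        if (yy < 0 || yy >= D.d1 || xx < 0 || xx >= D.d2 || zz < 0 ||
            zz >= D.d3)
          continue;
        R_xlen_t q = yy + (R_xlen_t)xx * D.d1 + (R_xlen_t)zz * sxy;
        if (mask[q] && !out[q]) {
          out[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  out.attr("dim") = mask.attr("dim");
  return out;
}

// Marker-controlled watershed: flood `elev` from the labelled seeds inside
// `mask`, assigning each element the label of the flood that reaches it
// first. Priority queue ordered by (elevation, insertion order), so equal
// elevations resolve first-come-first-served -- fully deterministic.
// [[Rcpp::export(name = ".watershed_cpp")]]
IntegerVector watershed_cpp(NumericVector elev, IntegerVector seeds,
                            IntegerVector mask, IntegerVector dims,
                            int conn) {
  Dims3 D(dims);
  bool is3d = D.d3 > 1;
  std::vector<std::array<int, 3>> offs = neigh_offsets(conn, is3d);
  IntegerVector out = clone(seeds);
  R_xlen_t sxy = (R_xlen_t)D.d1 * D.d2;

  struct Ent {
    double e;
    uint64_t ord;
    R_xlen_t idx;
    int lab;
  };
  struct Cmp {
    bool operator()(const Ent &a, const Ent &b) const {
      if (a.e != b.e) return a.e > b.e;
      return a.ord > b.ord;
    }
  };
  std::priority_queue<Ent, std::vector<Ent>, Cmp> pq;
  uint64_t cnt = 0;

  auto push_neighbours = [&](R_xlen_t p) {
    int y = (int)(p % D.d1);
    int x = (int)((p / D.d1) % D.d2);
    int z = (int)(p / sxy);
    for (auto &o : offs) {
      int yy = y + o[0], xx = x + o[1], zz = z + o[2];
      if (yy < 0 || yy >= D.d1 || xx < 0 || xx >= D.d2 || zz < 0 ||
          zz >= D.d3)
        continue;
      R_xlen_t q = yy + (R_xlen_t)xx * D.d1 + (R_xlen_t)zz * sxy;
      if (mask[q] && out[q] == 0)
        pq.push({elev[q], cnt++, q, out[p]});
    }
  };

  for (R_xlen_t i = 0; i < D.n; i++)
    if (out[i] > 0 && mask[i]) push_neighbours(i);

  while (!pq.empty()) {
    Ent e = pq.top();
    pq.pop();
    if (out[e.idx] != 0) continue;
    out[e.idx] = e.lab;
    push_neighbours(e.idx);
  }
  out.attr("dim") = seeds.attr("dim");
  return out;
}

// One-pass per-label statistics: voxel counts and tight bounding boxes
// (1-based, inclusive; columns y0,y1,x0,x1,z0,z1) for every positive label.
// [[Rcpp::export(name = ".label_stats_cpp")]]
List label_stats_cpp(IntegerVector labels, IntegerVector dims) {
  Dims3 D(dims);
  R_xlen_t sxy = (R_xlen_t)D.d1 * D.d2;
  int maxlab = 0;
  for (R_xlen_t i = 0; i < D.n; i++)
    if (labels[i] > maxlab) maxlab = labels[i];
  std::vector<double> cnt(maxlab + 1, 0);
  std::vector<int> y0(maxlab + 1, INT32_MAX), y1(maxlab + 1, -1),
      x0(maxlab + 1, INT32_MAX), x1(maxlab + 1, -1),
      z0(maxlab + 1, INT32_MAX), z1(maxlab + 1, -1);
  for (R_xlen_t i = 0; i < D.n; i++) {
    int l = labels[i];
    if (l <= 0) continue;
    int y = (int)(i % D.d1);
    int x = (int)((i / D.d1) % D.d2);
    int z = (int)(i / sxy);
    cnt[l]++;
    if (y < y0[l]) y0[l] = y;
    if (y > y1[l]) y1[l] = y;
    if (x < x0[l]) x0[l] = x;
    if (x > x1[l]) x1[l] = x;
    if (z < z0[l]) z0[l] = z;
    if (z > z1[l]) z1[l] = z;
  }
  std::vector<int> present;
  for (int l = 1; l <= maxlab; l++)
    if (cnt[l] > 0) present.push_back(l);
  int np = (int)present.size();
  IntegerVector ids(np);
  NumericVector vols(np);
  IntegerMatrix bbox(np, 6);
  for (int i = 0; i < np; i++) {
    int l = present[i];
    ids[i] = l;
    vols[i] = cnt[l];
    bbox(i, 0) = y0[l] + 1;
    bbox(i, 1) = y1[l] + 1;
    bbox(i, 2) = x0[l] + 1;
    bbox(i, 3) = x1[l] + 1;
    bbox(i, 4) = z0[l] + 1;
    bbox(i, 5) = z1[l] + 1;
  }
  return List::create(_["ids"] = ids, _["volumes"] = vols, _["bbox"] = bbox);
}
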