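// 3D morphology kernels for anisotropic confocal stacks.
// All arrays are column-major with dim = c(nx, ny, nz); linear index
// i + nx*(j + ny*k).  Connectivity is 26 throughout.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Finite stand-in for "no source on this line": far larger than any
// attainable squared distance, small enough for exact double arithmetic.
static const double BIG = 1e15;
static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) on a grid
// with sample spacing w.  f holds squared distances; result goes to d.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double xq = q * w, xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else { break; }
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

// Squared Euclidean distance from every voxel to the nearest TRUE voxel,
// with per-axis physical voxel sizes w = (wx, wy, wz).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector w) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : BIG;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());

  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, nx, w[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f, d, ny, w[1]);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)nx * j] = d[j];
    }
  // along z
  R_xlen_t stride = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      for (int k = 0; k < nz; ++k) f[k] = out[base + stride * k];
      dt1d(f, d, nz, w[2]);
      for (int k = 0; k < nz; ++k) out[base + stride * k] = d[k];
    }
  return out;
}

// Offsets of the 26-neighbourhood; fills dx/dy/dz.
static void neighbours26(int dx[26], int dy[26], int dz[26]) {
  int m = 0;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        dx[m] = a; dy[m] = b; dz[m] = c; ++m;
      }
}

// 26-connected component labelling; labels 1..K in raster-scan order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int dx[26], dy[26], dz[26];
  neighbours26(dx, dy, dz);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int i = v % nx, j = (v / nx) % ny, k = v / ((R_xlen_t)nx * ny);
      for (int m = 0; m < 26; ++m) {
        int ii = i + dx[m], jj = j + dy[m], kk = k + dz[m];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t u = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[u] && lab[u] == 0) {
          lab[u] = next;
          stack.push_back(u);
        }
      }
    }
  }
  return lab;
}

// Grayscale reconstruction by dilation of `marker` under `maskimg`
// (marker <= maskimg elementwise assumed).  Hybrid raster/anti-raster +
// FIFO algorithm (Vincent 1993), 26-connectivity.
// [[Rcpp::export]]
NumericVector cpp_reconstruct(NumericVector marker, NumericVector maskimg,
                              IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector J = clone(marker);
  int dx[26], dy[26], dz[26];
  neighbours26(dx, dy, dz);

  // raster scan: neighbours already visited (linear index smaller)
  for (R_xlen_t v = 0; v < n; ++v) {
    int i = v % nx, j = (v / nx) % ny, k = v / ((R_xlen_t)nx * ny);
    double m = J[v];
    for (int q = 0; q < 26; ++q) {
      int ii = i + dx[q], jj = j + dy[q], kk = k + dz[q];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      R_xlen_t u = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
      if (u < v && J[u] > m) m = J[u];
    }
    J[v] = std::min(m, maskimg[v]);
  }
  // anti-raster scan + queue
  std::queue<R_xlen_t> fifo;
  for (R_xlen_t v = n - 1; v >= 0; --v) {
    int i = v % nx, j = (v / nx) % ny, k = v / ((R_xlen_t)nx * ny);
    double m = J[v];
    bool enqueue = false;
    for (int q = 0; q < 26; ++q) {
      int ii = i + dx[q], jj = j + dy[q], kk = k + dz[q];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      R_xlen_t u = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
      if (u > v) {
        if (J[u] > m) m = J[u];
        if (J[u] < J[v] && J[u] < maskimg[u]) enqueue = true;
      }
    }
    J[v] = std::min(m, maskimg[v]);
    if (enqueue) fifo.push(v);
    if (v == 0) break;
  }
  while (!fifo.empty()) {
    R_xlen_t v = fifo.front();
    fifo.pop();
    int i = v % nx, j = (v / nx) % ny, k = v / ((R_xlen_t)nx * ny);
    for (int q = 0; q < 26; ++q) {
      int ii = i + dx[q], jj = j + dy[q], kk = k + dz[q];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      R_xlen_t u = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
      if (J[u] < J[v] && maskimg[u] != J[u]) {
        J[u] = std::min(J[v], maskimg[u]);
        fifo.push(u);
      }
    }
  }
  return J;
}

// Regional maxima of f restricted to mask: TRUE on plateaus with no
// strictly greater 26-neighbour inside the mask.
// [[Rcpp::export]]
LogicalVector cpp_regional_maxima(NumericVector f, LogicalVector mask,
                                  IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, 0);
  int dx[26], dy[26], dz[26];
  neighbours26(dx, dy, dz);
  // candidate: no greater neighbour
  std::vector<char> cand(n, 0);
  for (R_xlen_t v = 0; v < n; ++v) {
    if (!mask[v]) continue;
    int i = v % nx, j = (v / nx) % ny, k = v / ((R_xlen_t)nx * ny);
    bool ok = true;
    for (int q = 0; q < 26 && ok; ++q) {
      int ii = i + dx[q], jj = j + dy[q], kk = k + dz[q];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      R_xlen_t u = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
      if (mask[u] && f[u] > f[v]) ok = false;
    }
    cand[v] = ok;
  }
  // flood equal-value plateaus from candidates; a plateau survives only
  // if none of its members touches a greater neighbour
  std::vector<char> seen(n, 0);
  std::vector<R_xlen_t> stack, plateau;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!cand[s] || seen[s]) continue;
    double val = f[s];
    bool good = true;
    stack.clear(); plateau.clear();
    stack.push_back(s);
    seen[s] = 1;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      plateau.push_back(v);
      int i = v % nx, j = (v / nx) % ny, k = v / ((R_xlen_t)nx * ny);
      for (int q = 0; q < 26; ++q) {
        int ii = i + dx[q], jj = j + dy[q], kk = k + dz[q];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t u = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (!mask[u]) continue;
        if (f[u] > val) { good = false; continue; }
        if (f[u] == val && !seen[u]) {
          seen[u] = 1;
          stack.push_back(u);
        }
      }
    }
    if (good)
      for (size_t t = 0; t < plateau.size(); ++t) out[plateau[t]] = 1;
  }
  return out;
}

struct WsEntry {
  double prio;
  long long order;
  R_xlen_t idx;
  int label;
};
struct WsCmp {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.prio != b.prio) return a.prio < b.prio;   // max-heap on priority
    return a.order > b.order;                       // FIFO among ties
  }
};

// Marker-controlled watershed: flood `mask` from `markers` (labelled > 0)
// in order of decreasing f (f is typically a distance map).
// [[Rcpp::export]]
IntegerVector cpp_marker_watershed(NumericVector f, IntegerVector markers,
                                   LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab = clone(markers);
  int dx[26], dy[26], dz[26];
  neighbours26(dx, dy, dz);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  long long order = 0;

  for (R_xlen_t v = 0; v < n; ++v) {
    if (lab[v] <= 0) continue;
    int i = v % nx, j = (v / nx) % ny, k = v / ((R_xlen_t)nx * ny);
    for (int q = 0; q < 26; ++q) {
      int ii = i + dx[q], jj = j + dy[q], kk = k + dz[q];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      R_xlen_t u = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
      if (mask[u] && lab[u] == 0)
        pq.push(WsEntry{f[u], order++, u, lab[v]});
    }
  }
  while (!pq.empty()) {
    WsEntry e = pq.top();
    pq.pop();
    if (lab[e.idx] != 0) continue;
    lab[e.idx] = e.label;
    int i = e.idx % nx, j = (e.idx / nx) % ny, k = e.idx / ((R_xlen_t)nx * ny);
    for (int q = 0; q < 26; ++q) {
      int ii = i + dx[q], jj = j + dy[q], kk = k + dz[q];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      R_xlen_t u = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
      if (mask[u] && lab[u] == 0)
        pq.push(WsEntry{f[u], order++, u, e.label});
    }
  }
  return lab;
}

// Separable Gaussian blur with reflecting boundaries; sigma per axis in
// voxel units, kernel radius 3*sigma.
// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector img, IntegerVector dims,
                                NumericVector sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector cur = clone(img);
  int nd[3] = {nx, ny, nz};
  R_xlen_t strides[3] = {1, nx, (R_xlen_t)nx * ny};

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0 || nd[ax] == 1) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> kern(2 * r + 1);
    double tot = 0;
    for (int t = -r; t <= r; ++t) {
      kern[t + r] = std::exp(-0.5 * t * t / (s * s));
      tot += kern[t + r];
    }
    for (int t = 0; t <= 2 * r; ++t) kern[t] /= tot;

    NumericVector nxt(n);
    int len = nd[ax];
    R_xlen_t stride = strides[ax];
    // iterate over all lines along axis ax
    int o1 = (ax == 0) ? 1 : 0;               // first other axis
    int o2 = (ax == 2) ? 1 : 2;               // second other axis
    for (int b = 0; b < nd[o2]; ++b)
      for (int a = 0; a < nd[o1]; ++a) {
        R_xlen_t base = (R_xlen_t)a * strides[o1] + (R_xlen_t)b * strides[o2];
        for (int p = 0; p < len; ++p) {
          double acc = 0;
          for (int t = -r; t <= r; ++t) {
            int q = p + t;
            if (q < 0) q = -q - 1;                 // reflect
            if (q >= len) q = 2 * len - q - 1;
            if (q < 0) q = 0;
            if (q >= len) q = len - 1;
            acc += kern[t + r] * cur[base + stride * q];
          }
          nxt[base + stride * p] = acc;
        }
      }
    cur = nxt;
  }
  return cur;
}
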