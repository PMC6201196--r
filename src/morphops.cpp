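#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Union-find over flat pixel indices.
static int uf_find(std::vector<int>& parent, int x) {
  int root = x;
  while (parent[root] != root) root = parent[root];
  while (parent[x] != root) { int nxt = parent[x]; parent[x] = root; x = nxt; }
  return root;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Connected-component labelling of a binary image.
// dim: length 2 (rows, cols) or 3 (rows, cols, planes).
// connectivity: 4 or 8 in 2D, 6 in 3D. Column-major (R) layout.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector img, IntegerVector dim,
                                   int connectivity) {
  const int nr = dim[0], nc = dim[1];
  const int np = (dim.size() == 3) ? dim[2] : 1;
  const R_xlen_t n = (R_xlen_t)nr * nc * np;
  if (img.size() != n) stop("image size does not match dim");
  std::vector<int> parent(n);
  for (R_xlen_t i = 0; i < n; ++i) parent[i] = (int)i;

  const R_xlen_t plane_sz = (R_xlen_t)nr * nc;
  for (int p = 0; p < np; ++p) {
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        R_xlen_t i = p * plane_sz + (R_xlen_t)c * nr + r;
        if (!img[i]) continue;
        if (r > 0 && img[i - 1]) uf_union(parent, (int)i, (int)(i - 1));
        if (c > 0 && img[i - nr]) uf_union(parent, (int)i, (int)(i - nr));
        if (np > 1 && p > 0 && img[i - plane_sz])
          uf_union(parent, (int)i, (int)(i - plane_sz));
        if (connectivity == 8 && np == 1) {
          if (r > 0 && c > 0 && img[i - nr - 1])
            uf_union(parent, (int)i, (int)(i - nr - 1));
          if (r < nr - 1 && c > 0 && img[i - nr + 1])
            uf_union(parent, (int)i, (int)(i - nr + 1));
        }
      }
    }
  }

  IntegerVector out(n, 0);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!img[i]) continue;
    int root = uf_find(parent, (int)i);
    if (remap[root] == 0) remap[root] = ++next;
    out[i] = remap[root];
  }
  out.attr("dim") = dim;
  return out;
}

// Felzenszwalb & Huttenlocher 1D squared-distance pass on a sampled grid.
// f: input squared distances at positions x[i] (use DT_BIG, not infinity,
// for "no source here" so the envelope arithmetic stays finite); d: output.
static const double DT_BIG = 1e20;

static void dt_1d(const std::vector<double>& f, const std::vector<double>& x,
                  std::vector<double>& d) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  auto isect = [&](int q, int p) {
    return ((f[q] + x[q] * x[q]) - (f[p] + x[p] * x[p])) /
           (2.0 * x[q] - 2.0 * x[p]);
  };
  for (int q = 1; q < n; ++q) {
    double s = isect(q, v[k]);
    while (s <= z[k]) {
      --k;
      s = isect(q, v[k]);
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < x[q]) ++k;
    d[q] = (x[q] - x[v[k]]) * (x[q] - x[v[k]]) + f[v[k]];
  }
}

// Exact Euclidean distance transform: distance (in physical units) from each
// foreground pixel to the nearest background pixel centre. Background = 0.
// spacing: per-dimension physical step (rows, cols[, planes]).
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector fg, IntegerVector dim,
                      NumericVector spacing) {
  const int nd = dim.size();
  const int nr = dim[0], nc = dim[1];
  const int np = (nd == 3) ? dim[2] : 1;
  const R_xlen_t n = (R_xlen_t)nr * nc * np;
  if (fg.size() != n) stop("image size does not match dim");
  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = fg[i] ? DT_BIG : 0.0;

  const R_xlen_t plane_sz = (R_xlen_t)nr * nc;
  // pass along rows (down columns): stride 1
  {
    std::vector<double> f(nr), out(nr), x(nr);
    for (int r = 0; r < nr; ++r) x[r] = r * spacing[0];
    for (int p = 0; p < np; ++p)
      for (int c = 0; c < nc; ++c) {
        R_xlen_t base = p * plane_sz + (R_xlen_t)c * nr;
        bool any = false;
        for (int r = 0; r < nr; ++r) { f[r] = d[base + r]; if (f[r] != 0.0) any = true; }
        if (!any) continue;
        dt_1d(f, x, out);
        for (int r = 0; r < nr; ++r) d[base + r] = out[r];
      }
  }
  // pass along columns: stride nr
  {
    std::vector<double> f(nc), out(nc), x(nc);
    for (int c = 0; c < nc; ++c) x[c] = c * spacing[1];
    for (int p = 0; p < np; ++p)
      for (int r = 0; r < nr; ++r) {
        R_xlen_t base = p * plane_sz + r;
        for (int c = 0; c < nc; ++c) f[c] = d[base + (R_xlen_t)c * nr];
        dt_1d(f, x, out);
        for (int c = 0; c < nc; ++c) d[base + (R_xlen_t)c * nr] = out[c];
      }
  }
  // pass along planes
  if (np > 1) {
    std::vector<double> f(np), out(np), x(np);
    for (int p = 0; p < np; ++p) x[p] = p * spacing[2];
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        R_xlen_t base = (R_xlen_t)c * nr + r;
        for (int p = 0; p < np; ++p) f[p] = d[base + p * plane_sz];
        dt_1d(f, x, out);
        for (int p = 0; p < np; ++p) d[base + p * plane_sz] = out[p];
      }
  }

  NumericVector res(n);
  for (R_xlen_t i = 0; i < n; ++i)
    res[i] = (d[i] >= DT_BIG) ? R_PosInf : std::sqrt(d[i]);
  res.attr("dim") = dim;
  return res;
}

struct WsEntry {
  double elev;
  long long order;
  int idx;
  int label;
};
struct WsCmp {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.elev != b.elev) return a.elev > b.elev; // min-heap on elevation
    return a.order > b.order;                     // FIFO tie-break
  }
};

// Marker-controlled watershed (Meyer flooding) on a 2D elevation map,
// 4-connectivity, restricted to mask. markers: positive integer seeds.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector elev, IntegerVector dim,
                            IntegerVector markers, LogicalVector mask) {
  const int nr = dim[0], nc = dim[1];
  const R_xlen_t n = (R_xlen_t)nr * nc;
  if (elev.size() != n || markers.size() != n || mask.size() != n)
    stop("input sizes do not match dim");
  IntegerVector lab(n, 0);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  long long order = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (markers[i] > 0 && mask[i]) {
      lab[i] = markers[i];
      pq.push(WsEntry{elev[i], order++, (int)i, markers[i]});
    }
  }
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    WsEntry e = pq.top(); pq.pop();
    int r = e.idx % nr, c = e.idx / nr;
    for (int k = 0; k < 4; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      R_xlen_t j = (R_xlen_t)c2 * nr + r2;
      if (!mask[j] || lab[j] != 0) continue;
      lab[j] = e.label;
      pq.push(WsEntry{elev[j], order++, (int)j, e.label});
    }
  }
  lab.attr("dim") = dim;
  return lab;
}
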