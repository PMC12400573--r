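// n-dimensional (2D/3D) morphology primitives for spot calling:
//  - plateau-aware local maxima with full (8/26) connectivity
//  - connected-component labelling
//  - seeded watershed by priority flood (descending intensity)
// Arrays arrive as R column-major vectors with an explicit dim vector.

#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

struct Grid {
  std::vector<int> dim, stride;
  int nd = 0;
  R_xlen_t n = 0;
  Grid(const IntegerVector& d) {
    nd = d.size();
    dim.assign(d.begin(), d.end());
    stride.resize(nd);
    R_xlen_t s = 1;
    for (int i = 0; i < nd; ++i) { stride[i] = (int)s; s *= dim[i]; }
    n = s;
  }
  void coords(R_xlen_t idx, int* c) const {
    for (int i = 0; i < nd; ++i) { c[i] = idx % dim[i]; idx /= dim[i]; }
  }
  // full-connectivity neighbors of idx, appended to out
  void neighbors(R_xlen_t idx, std::vector<R_xlen_t>& out) const {
    out.clear();
    int c[8];
    coords(idx, c);
    int off[8];
    for (int i = 0; i < nd; ++i) off[i] = -1;
    while (true) {
      bool all0 = true, ok = true;
      R_xlen_t j = idx;
      for (int i = 0; i < nd; ++i) {
        if (off[i] != 0) all0 = false;
        const int cc = c[i] + off[i];
        if (cc < 0 || cc >= dim[i]) { ok = false; break; }
        j += (R_xlen_t)off[i] * stride[i];
      }
      if (ok && !all0) out.push_back(j);
      int i = 0;
      for (; i < nd; ++i) {
        if (off[i] < 1) { ++off[i]; break; }
        off[i] = -1;
      }
      if (i == nd) break;
    }
  }
};

// Plateau-aware local maxima: a maximal connected region of constant value,
// strictly greater than every neighboring pixel, yields one detection at the
// plateau centroid. Regions with value < min_value are skipped.
// [[Rcpp::export]]
NumericMatrix local_maxima_cpp(NumericVector x, IntegerVector dims,
                               double min_value) {
  Grid g(dims);
  std::vector<char> visited(g.n, 0);
  std::vector<R_xlen_t> nb, region, stack;
  std::vector<std::vector<double>> found;
  int c[8];
  for (R_xlen_t i = 0; i < g.n; ++i) {
    if (visited[i]) continue;
    const double v = x[i];
    if (v < min_value) { visited[i] = 1; continue; }
    // flood fill the constant-value plateau containing i
    region.clear();
    stack.clear();
    stack.push_back(i);
    visited[i] = 1;
    bool is_max = true;
    while (!stack.empty()) {
      R_xlen_t j = stack.back();
      stack.pop_back();
      region.push_back(j);
      g.neighbors(j, nb);
      for (R_xlen_t k : nb) {
        if (x[k] == v) {
          if (!visited[k]) { visited[k] = 1; stack.push_back(k); }
        } else if (x[k] > v) {
          is_max = false;
        }
      }
    }
    if (!is_max) continue;
    std::vector<double> cen(g.nd, 0.0);
    for (R_xlen_t j : region) {
      g.coords(j, c);
      for (int d = 0; d < g.nd; ++d) cen[d] += c[d];
    }
    for (int d = 0; d < g.nd; ++d) cen[d] /= region.size();
    cen.push_back(v);
    found.push_back(cen);
  }
  NumericMatrix out(found.size(), g.nd + 1);
  for (size_t r = 0; r < found.size(); ++r)
    for (int d = 0; d <= g.nd; ++d) out(r, d) = found[r][d];
  return out;
}

// Connected components of a logical mask under full connectivity.
// Returns 0 for background, 1..k for components.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  Grid g(dims);
  IntegerVector lab(g.n, 0);
  std::vector<R_xlen_t> nb, stack;
  int next = 0;
  for (R_xlen_t i = 0; i < g.n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      R_xlen_t j = stack.back();
      stack.pop_back();
      g.neighbors(j, nb);
      for (R_xlen_t k : nb)
        if (mask[k] && lab[k] == 0) { lab[k] = next; stack.push_back(k); }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Seeded watershed by priority flood restricted to a mask: basins grow from
// the seed pixels outward in order of descending image intensity (FIFO on
// ties for determinism). Returns basin labels (0 outside mask / unreached).
// [[Rcpp::export]]
IntegerVector watershed_seeded_cpp(NumericVector x, LogicalVector mask,
                                   IntegerVector dims,
                                   IntegerVector seed_idx) {
  Grid g(dims);
  IntegerVector lab(g.n, 0);
  struct QE { double v; R_xlen_t order; R_xlen_t idx; int label; };
  struct Cmp {
    bool operator()(const QE& a, const QE& b) const {
      if (a.v != b.v) return a.v < b.v;       // higher intensity first
      return a.order > b.order;               // FIFO on ties
    }
  };
  std::priority_queue<QE, std::vector<QE>, Cmp> pq;
  R_xlen_t ord = 0;
  for (int s = 0; s < seed_idx.size(); ++s) {
    R_xlen_t i = seed_idx[s];
    pq.push({x[i], ord++, i, s + 1});
  }
  std::vector<R_xlen_t> nb;
  while (!pq.empty()) {
    QE e = pq.top();
    pq.pop();
    if (lab[e.idx] != 0) continue;
    lab[e.idx] = e.label;
    g.neighbors(e.idx, nb);
    for (R_xlen_t k : nb)
      if (mask[k] && lab[k] == 0) pq.push({x[k], ord++, k, e.label});
  }
  lab.attr("dim") = dims;
  return lab;
}

// CRC-32 (IEEE 802.3), needed by the minimal ZIP/NPZ writer.
// [[Rcpp::export]]
double crc32_cpp(RawVector bytes) {
  static uint32_t table[256];
  static bool have_table = false;
  if (!have_table) {
    for (uint32_t b = 0; b < 256; ++b) {
      uint32_t r = b;
      for (int j = 0; j < 8; ++j)
        r = (r & 1) ? (r >> 1) ^ 0xEDB88320u : (r >> 1);
      table[b] = r;
    }
    have_table = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < bytes.size(); ++i)
    crc = (crc >> 8) ^ table[(crc ^ bytes[i]) & 0xFFu];
  return (double)(crc ^ 0xFFFFFFFFu);
}
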