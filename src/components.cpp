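#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 6-connected component labelling and depth-limited region growing.

// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dim) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  R_xlen_t nvox = (R_xlen_t)d1 * d2 * d3;
  IntegerVector labels(nvox);
  const int *m = mask.begin();
  int *lab = labels.begin();
  const R_xlen_t s3 = (R_xlen_t)d1 * d2;
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t v0 = 0; v0 < nvox; ++v0) {
    if (!m[v0] || lab[v0]) continue;
    ++next;
    lab[v0] = next;
    q.push(v0);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int i = (int)(v % d1), j = (int)((v / d1) % d2), k = (int)(v / s3);
      R_xlen_t nb[6]; int nn = 0;
      if (i > 0)      nb[nn++] = v - 1;
      if (i < d1 - 1) nb[nn++] = v + 1;
      if (j > 0)      nb[nn++] = v - d1;
      if (j < d2 - 1) nb[nn++] = v + d1;
      if (k > 0)      nb[nn++] = v - s3;
      if (k < d3 - 1) nb[nn++] = v + s3;
      for (int t = 0; t < nn; ++t)
        if (m[nb[t]] && !lab[nb[t]]) { lab[nb[t]] = next; q.push(nb[t]); }
    }
  }
  labels.attr("n_components") = next;
  return labels;
}

// breadth-first growth from a seed through in-range voxels, accepting one
// 6-connected dilation layer per iteration, up to max_layers layers
// [[Rcpp::export]]
IntegerVector cpp_region_grow(IntegerVector inrange, IntegerVector dim,
                              R_xlen_t seed, int max_layers) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  R_xlen_t nvox = (R_xlen_t)d1 * d2 * d3;
  IntegerVector out(nvox);
  const int *m = inrange.begin();
  int *o = out.begin();
  const R_xlen_t s3 = (R_xlen_t)d1 * d2;
  if (seed < 0 || seed >= nvox || !m[seed]) stop("seed voxel not in range");
  std::vector<R_xlen_t> frontier(1, seed);
  o[seed] = 1;
  for (int layer = 0; layer < max_layers && !frontier.empty(); ++layer) {
    std::vector<R_xlen_t> nxt;
    for (size_t t = 0; t < frontier.size(); ++t) {
      R_xlen_t v = frontier[t];
      int i = (int)(v % d1), j = (int)((v / d1) % d2), k = (int)(v / s3);
      R_xlen_t nb[6]; int nn = 0;
      if (i > 0)      nb[nn++] = v - 1;
      if (i < d1 - 1) nb[nn++] = v + 1;
      if (j > 0)      nb[nn++] = v - d1;
      if (j < d2 - 1) nb[nn++] = v + d1;
      if (k > 0)      nb[nn++] = v - s3;
      if (k < d3 - 1) nb[nn++] = v + s3;
      for (int u = 0; u < nn; ++u)
        if (m[nb[u]] && !o[nb[u]]) { o[nb[u]] = 1; nxt.push_back(nb[u]); }
    }
    frontier.swap(nxt);
  }
  return out;
}
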