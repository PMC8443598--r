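#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Threshold-free cluster enhancement of the positive tail of a statistic
// map on a parcel graph. For each parcel p,
//   TFCE(p) = sum_{h = dh, 2dh, ... <= max t} extent(p, h)^E * h^H * dh,
// where extent(p, h) is the size of the connected suprathreshold
// (t >= h) component containing p. Thresholds are processed in descending
// order with a union-find so components grow monotonically.
// `from`/`to` are 1-based parcel indices of the adjacency edges.
// [[Rcpp::export]]
NumericVector tfce_positive(NumericVector t, IntegerVector from,
                            IntegerVector to, double E, double H,
                            double dh) {
  const int P = t.size();
  NumericVector enh(P);
  double tmax = 0.0;
  for (int i = 0; i < P; ++i)
    if (t[i] > tmax) tmax = t[i];
  if (tmax <= 0.0 || dh <= 0.0) return enh;

  std::vector<std::vector<int>> adj(P);
  for (int i = 0; i < from.size(); ++i) {
    int a = from[i] - 1, b = to[i] - 1;
    adj[a].push_back(b);
    adj[b].push_back(a);
  }

  std::vector<int> order(P);
  for (int i = 0; i < P; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return t[a] > t[b]; });

  std::vector<int> parent(P, -1), csize(P, 0);
  std::vector<char> active(P, 0);

  int smax = (int)std::floor(tmax / dh + 1e-12);
  int ptr = 0;
  for (int s = smax; s >= 1; --s) {
    double h = s * dh;
    while (ptr < P && t[order[ptr]] >= h) {
      int nd = order[ptr];
      parent[nd] = nd;
      csize[nd] = 1;
      active[nd] = 1;
      for (int nb : adj[nd]) {
        if (!active[nb]) continue;
        int ra = uf_find(parent, nd), rb = uf_find(parent, nb);
        if (ra != rb) {
          if (csize[ra] < csize[rb]) std::swap(ra, rb);
          parent[rb] = ra;
          csize[ra] += csize[rb];
        }
      }
      ++ptr;
    }
    double hH = std::pow(h, H) * dh;
    for (int i = 0; i < ptr; ++i) {
      int nd = order[i];
      enh[nd] += std::pow((double)csize[uf_find(parent, nd)], E) * hH;
    }
  }
  return enh;
}
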