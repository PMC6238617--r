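#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  const int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra < rb) parent[rb] = ra; else parent[ra] = rb;
}

// Two-pass connected-component labeling of a logical mask under 4- or
// 8-connectivity. Final labels are consecutive 1..n in column-major scan
// order of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask,
                                   const int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0);  // label 0 = background, self-parent
  int next = 1;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int best = 0;
      // previously scanned neighbours in column-major order
      int ndy[4], ndx[4], nn = 0;
      ndy[nn] = -1; ndx[nn] = 0; ++nn;           // above in same column
      ndy[nn] = 0;  ndx[nn] = -1; ++nn;          // same row, previous column
      if (connectivity == 8) {
        ndy[nn] = -1; ndx[nn] = -1; ++nn;
        ndy[nn] = 1;  ndx[nn] = -1; ++nn;
      }
      for (int o = 0; o < nn; ++o) {
        const int ii = i + ndy[o], jj = j + ndx[o];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        const int l = lab(ii, jj);
        if (l == 0) continue;
        if (best == 0) best = l;
        else if (l != best) { uf_union(parent, best, l); if (l < best) best = l; }
      }
      if (best == 0) {
        parent.push_back(next);
        lab(i, j) = next++;
      } else {
        lab(i, j) = best;
      }
    }
  }

  // resolve equivalences, renumber consecutively in scan order
  std::vector<int> remap(next, 0);
  int count = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const int l = lab(i, j);
      if (l == 0) continue;
      const int r = uf_find(parent, l);
      if (remap[r] == 0) remap[r] = ++count;
      lab(i, j) = remap[r];
    }
  }
  return lab;
}
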