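#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// 6-connected component labelling of a 3D logical array (two-pass
// union-find). Returns integer labels, 0 for background.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(mask.size());
  std::vector<int> parent(1, 0);
  auto find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  size_t q = 0;
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix, ++q) {
        if (!mask[q]) { lab[q] = 0; continue; }
        int lx = (ix > 0 && mask[q - 1]) ? lab[q - 1] : 0;
        int ly = (iy > 0 && mask[q - nx]) ? lab[q - nx] : 0;
        int lz = (iz > 0 && mask[q - (size_t)nx * ny]) ?
                 lab[q - (size_t)nx * ny] : 0;
        int l = 0;
        if (lx) l = lx;
        if (ly) l = l ? std::min(l, ly) : ly;
        if (lz) l = l ? std::min(l, lz) : lz;
        if (!l) {
          l = (int)parent.size();
          parent.push_back(l);
        }
        if (lx) unite(l, lx);
        if (ly) unite(l, ly);
        if (lz) unite(l, lz);
        lab[q] = l;
      }
  // second pass: canonical labels, renumbered consecutively
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (size_t i = 0; i < n; ++i) {
    if (!lab[i]) continue;
    int r = find(lab[i]);
    if (!remap[r]) remap[r] = ++next;
    lab[i] = remap[r];
  }
  lab.attr("dim") = dims;
  return lab;
}
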