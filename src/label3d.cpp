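#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling of a logical array by breadth-first
// search. connectivity is 6 (faces) or 26 (faces+edges+corners). Labels are
// assigned in scan order starting at 1; background (FALSE/NA) is 0.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dim,
                          int connectivity = 26) {
  if (dim.size() != 3) stop("dim must have length 3");
  const int nz = dim[0], nx = dim[1], ny = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * nx * ny;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  IntegerVector lab(n, 0);
  lab.attr("dim") = dim;

  // neighbour offsets in (z,x,y)
  std::vector<int> dz, dx, dy;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        dz.push_back(a); dx.push_back(b); dy.push_back(c);
      }
  const int nnb = (int)dz.size();

  std::vector<R_xlen_t> queue;
  int next_label = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] != TRUE || lab[i] != 0) continue;
    ++next_label;
    lab[i] = next_label;
    queue.clear();
    queue.push_back(i);
    while (!queue.empty()) {
      R_xlen_t cur = queue.back();
      queue.pop_back();
      int z = (int)(cur % nz);
      int x = (int)((cur / nz) % nx);
      int y = (int)(cur / ((R_xlen_t)nz * nx));
      for (int k = 0; k < nnb; ++k) {
        int zz = z + dz[k], xx = x + dx[k], yy = y + dy[k];
        if (zz < 0 || zz >= nz || xx < 0 || xx >= nx || yy < 0 || yy >= ny)
          continue;
        R_xlen_t j = (R_xlen_t)zz + (R_xlen_t)nz * (xx + (R_xlen_t)nx * yy);
        if (mask[j] == TRUE && lab[j] == 0) {
          lab[j] = next_label;
          queue.push_back(j);
        }
      }
    }
  }
  return lab;
}
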