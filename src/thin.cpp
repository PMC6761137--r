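#include <Rcpp.h>
using namespace Rcpp;

// 8-neighborhood in raster order; bit k of a configuration code is set when
// the corresponding neighbor is foreground. Must stay in sync with the R-side
// LUT builders (neighbor_offsets() in R/skeleton.R).
static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Sequential homotopic thinning by simple-point deletion. `deletable` is a
// 256-entry lookup table over neighbor configuration codes, true when the
// center pixel is a simple point with 2..7 foreground neighbors (endpoints
// and isolated pixels are kept). Four directional sub-passes (N, S, E, W
// border pixels) per iteration give an approximately medial result; deletion
// is immediate, so connectivity is preserved exactly.
// [[Rcpp::export(name = ".thin_cpp")]]
LogicalMatrix thin_cpp(const LogicalMatrix& mask, const LogicalVector& deletable) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> img((size_t)nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      img[(size_t)i + (size_t)j * nr] = mask(i, j) ? 1 : 0;

  auto at = [&](int i, int j) -> char {
    if (i < 0 || j < 0 || i >= nr || j >= nc) return 0;
    return img[(size_t)i + (size_t)j * nr];
  };

  // background required at: N, S, E, W
  static const int pdr[4] = {-1, 1, 0, 0};
  static const int pdc[4] = {0, 0, 1, -1};

  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 4; ++d) {
      for (int i = 0; i < nr; ++i) {
        for (int j = 0; j < nc; ++j) {
          if (!img[(size_t)i + (size_t)j * nr]) continue;
          if (at(i + pdr[d], j + pdc[d])) continue;
          int code = 0;
          for (int k = 0; k < 8; ++k)
            if (at(i + DR[k], j + DC[k])) code |= (1 << k);
          if (deletable[code]) {
            img[(size_t)i + (size_t)j * nr] = 0;
            changed = true;
          }
        }
      }
    }
  }

  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = img[(size_t)i + (size_t)j * nr] != 0;
  return out;
}
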