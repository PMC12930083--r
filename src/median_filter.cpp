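#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// 3x3x3 median filter restricted to a mask: each in-mask voxel is replaced
// by the median of the in-mask voxels in its 26-neighbourhood (plus
// itself); out-of-mask voxels are left untouched (NA in practice).
// [[Rcpp::export(name = ".median_filter3")]]
NumericVector median_filter3(NumericVector vol, LogicalVector mask,
                             IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericVector out = clone(vol);
  std::vector<double> buf;
  buf.reserve(27);
  for (int z = 0; z < n3; ++z) {
    for (int y = 0; y < n2; ++y) {
      for (int x = 0; x < n1; ++x) {
        const int idx = x + n1 * (y + n2 * z);
        if (!mask[idx]) continue;
        buf.clear();
        for (int dz = -1; dz <= 1; ++dz) {
          const int zz = z + dz;
          if (zz < 0 || zz >= n3) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            const int yy = y + dy;
            if (yy < 0 || yy >= n2) continue;
            for (int dx = -1; dx <= 1; ++dx) {
              const int xx = x + dx;
              if (xx < 0 || xx >= n1) continue;
              const int j = xx + n1 * (yy + n2 * zz);
              if (mask[j] && !NumericVector::is_na(vol[j])) {
                buf.push_back(vol[j]);
              }
            }
          }
        }
        if (buf.empty()) continue;
        const size_t h = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + h, buf.end());
        double med = buf[h];
        if (buf.size() % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + h - 1, buf.begin() + h);
          med = 0.5 * (med + buf[h - 1]);
        }
        out[idx] = med;
      }
    }
  }
  return out;
}
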