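#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sliding-histogram (Huang) median filter over a disk neighbourhood.
// Intensities are quantised to n_bins equal-width bins over the image
// range; the returned median is the centre of the median bin, so the
// approximation error is bounded by half a bin width. Pixels outside the
// image are excluded from the window.
// [[Rcpp::export]]
NumericMatrix cpp_disk_median(const NumericMatrix& img,
                              const double radius_px,
                              const int n_bins) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);

  double lo = img(0, 0), hi = img(0, 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      const double v = img(i, j);
      if (v < lo) lo = v;
      if (v > hi) hi = v;
    }
  if (hi == lo) {
    std::fill(out.begin(), out.end(), lo);
    return out;
  }
  const double w = (hi - lo) / n_bins;
  IntegerMatrix bin(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int b = (int)std::floor((img(i, j) - lo) / w);
      if (b >= n_bins) b = n_bins - 1;
      bin(i, j) = b;
    }

  const int r = (int)std::floor(radius_px);
  std::vector<int> dymax(2 * r + 1);
  for (int dx = -r; dx <= r; ++dx)
    dymax[dx + r] = (int)std::floor(std::sqrt(
        radius_px * radius_px - (double)dx * dx));

  std::vector<int> hist(n_bins);
  for (int j = 0; j < nc; ++j) {
    std::fill(hist.begin(), hist.end(), 0);
    int count = 0;
    // window centred at (0, j)
    for (int dx = -r; dx <= r; ++dx) {
      const int jj = j + dx;
      if (jj < 0 || jj >= nc) continue;
      const int dm = dymax[dx + r];
      for (int ii = 0; ii <= dm && ii < nr; ++ii) {
        ++hist[bin(ii, jj)];
        ++count;
      }
    }
    for (int i = 0; i < nr; ++i) {
      if (i > 0) {
        for (int dx = -r; dx <= r; ++dx) {
          const int jj = j + dx;
          if (jj < 0 || jj >= nc) continue;
          const int dm = dymax[dx + r];
          const int drop = i - 1 - dm, add = i + dm;
          if (drop >= 0) { --hist[bin(drop, jj)]; --count; }
          if (add < nr) { ++hist[bin(add, jj)]; ++count; }
        }
      }
      const int k = (count + 1) / 2;  // lower median
      int cum = 0, b = 0;
      for (; b < n_bins; ++b) {
        cum += hist[b];
        if (cum >= k) break;
      }
      out(i, j) = lo + (b + 0.5) * w;
    }
  }
  return out;
}
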