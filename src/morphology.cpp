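#include <Rcpp.h>
using namespace Rcpp;

// Flat greyscale erosion/dilation by an arbitrary structuring element given
// as pixel offsets (dy, dx). Offsets falling outside the image are ignored,
// i.e. the operators are restricted to the image domain; with a symmetric
// element this keeps opening anti-extensive (opening <= image) everywhere,
// including at the borders.
// [[Rcpp::export]]
NumericMatrix cpp_grey_morph(const NumericMatrix& img,
                             const IntegerVector& dy,
                             const IntegerVector& dx,
                             const bool erode) {
  const int nr = img.nrow(), nc = img.ncol(), k = dy.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = erode ? R_PosInf : R_NegInf;
      for (int o = 0; o < k; ++o) {
        const int ii = i + dy[o], jj = j + dx[o];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        const double v = img(ii, jj);
        if (erode ? (v < acc) : (v > acc)) acc = v;
      }
      out(i, j) = acc;
    }
  }
  return out;
}
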