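#include <Rcpp.h>
using namespace Rcpp;

// Separable Gaussian convolution with mirror boundary handling.
// Kernel truncated at 3 sigma, renormalised to sum 1.
// [[Rcpp::export]]
NumericMatrix gaussBlurSep(const NumericMatrix& img, double sigma) {
  if (sigma <= 0) stop("sigma must be positive");
  int radius = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + radius];
  }
  for (size_t i = 0; i < k.size(); ++i) k[i] /= s;

  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix tmp(nr, nc), out(nr, nc);

  // pass 1: along rows (first index)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -radius; t <= radius; ++t) {
        int ii = i + t;
        if (ii < 0) ii = -ii - 1;
        else if (ii >= nr) ii = 2 * nr - ii - 1;
        acc += k[t + radius] * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  }
  // pass 2: along columns (second index)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -radius; t <= radius; ++t) {
        int jj = j + t;
        if (jj < 0) jj = -jj - 1;
        else if (jj >= nc) jj = 2 * nc - jj - 1;
        acc += k[t + radius] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  }
  return out;
}
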