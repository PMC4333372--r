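#include <Rcpp.h>
using namespace Rcpp;

// Zero-mean normalized cross-correlation (Pearson correlation) between a
// template and every same-size patch of an image. Output (i, j) corresponds
// to the patch whose top-left pixel is image(i, j) (0-based); i.e. the map
// has dimensions (nrow - tr + 1) x (ncol - tc + 1). Patches (or templates)
// with vanishing variance yield 0 by convention.

// [[Rcpp::export(name = ".znccMapCpp")]]
NumericMatrix znccMapCpp(NumericMatrix image, NumericMatrix tmpl) {
  const int nr = image.nrow(), nc = image.ncol();
  const int tr = tmpl.nrow(), tc = tmpl.ncol();
  if (tr > nr || tc > nc)
    stop("image must be at least as large as the template");
  const int n = tr * tc;
  const double eps = 1e-12;

  // template statistics
  double tmean = 0.0;
  for (int j = 0; j < tc; ++j)
    for (int i = 0; i < tr; ++i) tmean += tmpl(i, j);
  tmean /= n;
  double tss = 0.0;
  std::vector<double> tz(n);
  for (int j = 0; j < tc; ++j)
    for (int i = 0; i < tr; ++i) {
      double v = tmpl(i, j) - tmean;
      tz[j * tr + i] = v;
      tss += v * v;
    }
  const bool tconst = tss < eps;

  const int mr = nr - tr + 1, mc = nc - tc + 1;
  NumericMatrix out(mr, mc);
  for (int pj = 0; pj < mc; ++pj) {
    for (int pi = 0; pi < mr; ++pi) {
      double s = 0.0, ss = 0.0, cross = 0.0;
      for (int j = 0; j < tc; ++j) {
        for (int i = 0; i < tr; ++i) {
          double v = image(pi + i, pj + j);
          s += v;
          ss += v * v;
          cross += v * tz[j * tr + i];
        }
      }
      double pvar = ss - s * s / n;  // cross already template-zero-mean
      if (tconst || pvar < eps) {
        out(pi, pj) = 0.0;
      } else {
        out(pi, pj) = cross / std::sqrt(pvar * tss);
      }
    }
  }
  return out;
}
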