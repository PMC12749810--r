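#include <Rcpp.h>
using namespace Rcpp;

// Non-local-means denoising, per-offset integral-image formulation.
//
// For every search offset the squared-difference image is box-filtered over
// the patch window via a summed-area table, giving the mean squared patch
// distance for all pixels of that offset at O(N) instead of O(N * patch^2).
// Weights follow w = exp(-max(d2 - 2*sigma^2, 0) / h^2).  The patch
// distance is symmetric, so each offset pair (o, -o) is processed once and
// contributes to both endpoints; the exponential is a 4096-entry lookup
// table.  Borders are handled by coordinate clamping.
// [[Rcpp::export]]
NumericMatrix nlm_denoise_cpp(NumericMatrix img, double sigma, double h,
                              int patch_radius, int search_radius) {
  const int nr = img.nrow(), nc = img.ncol();
  const size_t N = (size_t)nr * nc;
  NumericMatrix acc(nr, nc), wsum(nr, nc);
  std::vector<double> diff2(N), sat((size_t)(nr + 1) * (nc + 1));
  const double sigma2 = 2.0 * sigma * sigma, h2 = h * h;
  const int pr = patch_radius;
  const double patch_n = (2.0 * pr + 1) * (2.0 * pr + 1);

  // exp(-x) lookup on x in [0, 12], clamped beyond
  const int TN = 4096;
  const double xmax = 12.0, xstep = xmax / TN;
  std::vector<double> etab(TN + 1);
  for (int k = 0; k <= TN; ++k) etab[k] = exp(-k * xstep);
  const double *im = img.begin();
  double *ac = acc.begin(), *ws = wsum.begin();

  // self weight
  for (size_t k = 0; k < N; ++k) { ac[k] += im[k]; ws[k] += 1.0; }

  for (int dx = -search_radius; dx <= search_radius; ++dx) {
    for (int dy = -search_radius; dy <= search_radius; ++dy) {
      if (dx < 0 || (dx == 0 && dy <= 0)) continue;  // half-space
      // squared differences against the shifted image (clamped indices)
      for (int j = 0; j < nc; ++j) {
        int js = std::min(std::max(j + dx, 0), nc - 1);
        const double *c0 = im + (size_t)j * nr, *c1 = im + (size_t)js * nr;
        double *dd = diff2.data() + (size_t)j * nr;
        int i0 = std::max(0, -dy), i1 = std::min(nr, nr - dy);
        for (int i = 0; i < i0; ++i) {
          double d = c0[i] - c1[0]; dd[i] = d * d;
        }
        for (int i = i0; i < i1; ++i) {
          double d = c0[i] - c1[i + dy]; dd[i] = d * d;
        }
        for (int i = i1; i < nr; ++i) {
          double d = c0[i] - c1[nr - 1]; dd[i] = d * d;
        }
      }
      // summed-area table
      for (int j = 0; j <= nc; ++j) sat[(size_t)j * (nr + 1)] = 0.0;
      for (int i = 0; i <= nr; ++i) sat[i] = 0.0;
      for (int j = 1; j <= nc; ++j) {
        double col = 0.0;
        double *sj = sat.data() + (size_t)j * (nr + 1);
        const double *sp = sj - (nr + 1);
        const double *dd = diff2.data() + (size_t)(j - 1) * nr;
        for (int i = 1; i <= nr; ++i) {
          col += dd[i - 1];
          sj[i] = sp[i] + col;
        }
      }
      // accumulate both members of the offset pair
      for (int j = 0; j < nc; ++j) {
        int j0 = std::max(j - pr, 0), j1 = std::min(j + pr, nc - 1);
        int js = std::min(std::max(j + dx, 0), nc - 1);
        const double *sA = sat.data() + (size_t)(j1 + 1) * (nr + 1);
        const double *sB = sat.data() + (size_t)j0 * (nr + 1);
        for (int i = 0; i < nr; ++i) {
          int i0 = std::max(i - pr, 0), i1 = std::min(i + pr, nr - 1);
          double s = sA[i1 + 1] - sB[i1 + 1] - sA[i0] + sB[i0];
          double e = s / patch_n - sigma2;
          double w;
          if (e <= 0) w = 1.0;
          else {
            double x = e / h2;
            w = x >= xmax ? etab[TN] : etab[(int)(x / xstep)];
          }
          int is = std::min(std::max(i + dy, 0), nr - 1);
          size_t p = (size_t)j * nr + i, q = (size_t)js * nr + is;
          ac[p] += w * im[q]; ws[p] += w;
          ac[q] += w * im[p]; ws[q] += w;
        }
      }
    }
  }
  NumericMatrix out(nr, nc);
  for (size_t k = 0; k < N; ++k) out.begin()[k] = ac[k] / ws[k];
  return out;
}
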