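#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Symmetric (mirror, edge-inclusive) reflection of 0-based index i into [0, n)
static inline int reflect0(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  int j = i % period;
  if (j < 0) j += period;
  return (j < n) ? j : period - 1 - j;
}

// Neighborhood similarity filter (non-local means form).
// img: 2-D slice; patch/search: odd window sides; h: smoothing strength;
// kern: patch x patch Gaussian offset weights summing to 1.
// Returns the filtered slice with attribute "pixel_visits": the instrumented
// count of patch-pixel reads executed by the distance loops.
// [[Rcpp::export]]
NumericMatrix nlm_core(NumericMatrix img, int patch, int search, double h,
                       NumericMatrix kern) {
  const int nr = img.nrow(), nc = img.ncol();
  const int pr = patch / 2, sr = search / 2, pad = pr + sr;
  const int Nr = nr + 2 * pad, Nc = nc + 2 * pad;
  const double ih2 = 1.0 / (h * h);

  // Reflect-pad once so the hot loops are branch-free.
  std::vector<double> P((size_t)Nr * Nc);
  for (int c = 0; c < Nc; ++c) {
    const int sc = reflect0(c - pad, nc);
    double* col = &P[(size_t)c * Nr];
    for (int r = 0; r < Nr; ++r) col[r] = img(reflect0(r - pad, nr), sc);
  }

  NumericMatrix out(nr, nc);
  const double* K = kern.begin();
  double visits = 0.0;

  for (int j = 0; j < nc; ++j) {
    const int tj = j + pad;
    for (int i = 0; i < nr; ++i) {
      const int ti = i + pad;
      double acc = 0.0, Z = 0.0;
      for (int dj = -sr; dj <= sr; ++dj) {
        for (int di = -sr; di <= sr; ++di) {
          double d2 = 0.0;
          const double* a0 = &P[(size_t)(tj - pr) * Nr + (ti - pr)];
          const double* b0 = &P[(size_t)(tj + dj - pr) * Nr + (ti + di - pr)];
          const double* k0 = K;
          for (int q = 0; q < patch; ++q) {
            const double* a = a0 + (size_t)q * Nr;
            const double* b = b0 + (size_t)q * Nr;
            for (int p = 0; p < patch; ++p) {
              const double diff = a[p] - b[p];
              d2 += k0[p] * diff * diff;
            }
            k0 += patch;
          }
          const double w = std::exp(-d2 * ih2);
          acc += w * P[(size_t)(tj + dj) * Nr + (ti + di)];
          Z += w;
        }
      }
      out(i, j) = acc / Z;
      visits += (double)search * search * patch * patch;
    }
  }
  out.attr("pixel_visits") = visits;
  return out;
}
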