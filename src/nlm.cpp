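#include <Rcpp.h>
using namespace Rcpp;

// Symmetric (mirror, edge-included) index into [0, n)
static inline int refl(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Non-local means on a single slice.
//
// For each pixel p, the output is the weighted average of all pixels q in a
// (2*search_r+1)^2 search window, with weights
//   w(p,q) = exp(-d2(p,q) / h^2),
// where d2 is the mean squared difference between the (2*patch_r+1)^2
// patches centred at p and q. The self weight is set to the maximum weight
// among the other candidates (standard practice so the centre pixel does not
// dominate). Borders are handled by symmetric reflection.
//
// Computed by offset decomposition: for every search offset the squared
// difference image is box-filtered separably, yielding all patch distances
// for that offset at once.
// [[Rcpp::export]]
NumericMatrix nlm_denoise_slice(NumericMatrix img, int patch_r, int search_r,
                                double h) {
  const int nr = img.nrow(), nc = img.ncol();
  const int R = patch_r + search_r;
  const int pr = patch_r, psz = (2 * pr + 1) * (2 * pr + 1);
  const double h2 = h * h;

  // padded copy
  const int Pr = nr + 2 * R, Pc = nc + 2 * R;
  std::vector<double> P((size_t)Pr * Pc);
  for (int j = 0; j < Pc; ++j) {
    const int js = refl(j - R, nc);
    for (int i = 0; i < Pr; ++i)
      P[(size_t)j * Pr + i] = img(refl(i - R, nr), js);
  }

  const int Ar = nr + 2 * pr, Ac = nc + 2 * pr;
  std::vector<double> D((size_t)Ar * Ac), tmp((size_t)Ar * nc);
  std::vector<double> acc((size_t)nr * nc, 0.0), wsum((size_t)nr * nc, 0.0),
      wmax((size_t)nr * nc, 0.0);

  for (int dj = -search_r; dj <= search_r; ++dj) {
    for (int di = -search_r; di <= search_r; ++di) {
      if (di == 0 && dj == 0) continue;
      // squared differences, shifted grid (a,b) -> padded (a+sr, b+sr)
      for (int b = 0; b < Ac; ++b) {
        const double *p0 = &P[(size_t)(b + search_r) * Pr + search_r];
        const double *p1 = &P[(size_t)(b + search_r + dj) * Pr + search_r + di];
        double *d = &D[(size_t)b * Ar];
        for (int a = 0; a < Ar; ++a) {
          const double v = p0[a] - p1[a];
          d[a] = v * v;
        }
      }
      // box filter: columns then rows
      for (int j = 0; j < nc; ++j) {
        double *t = &tmp[(size_t)j * Ar];
        const double *d0 = &D[(size_t)j * Ar];
        for (int a = 0; a < Ar; ++a) {
          double s = 0.0;
          for (int tt = 0; tt <= 2 * pr; ++tt)
            s += d0[(size_t)tt * Ar + a];
          t[a] = s;
        }
      }
      for (int j = 0; j < nc; ++j) {
        const double *t = &tmp[(size_t)j * Ar];
        const double *pn = &P[(size_t)(j + R + dj) * Pr + R + di];
        double *ac = &acc[(size_t)j * nr];
        double *ws = &wsum[(size_t)j * nr];
        double *wm = &wmax[(size_t)j * nr];
        for (int i = 0; i < nr; ++i) {
          double s = 0.0;
          for (int tt = 0; tt <= 2 * pr; ++tt) s += t[i + tt];
          const double d2 = s / psz;
          double w;
          if (h2 > 0.0) w = std::exp(-d2 / h2);
          else w = (d2 == 0.0) ? 1.0 : 0.0;
          if (w > wm[i]) wm[i] = w;
          ws[i] += w;
          ac[i] += w * pn[i];
        }
      }
    }
  }

  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const size_t k = (size_t)j * nr + i;
      double wm = wmax[k] > 0.0 ? wmax[k] : 1.0;
      out(i, j) = (acc[k] + wm * img(i, j)) / (wsum[k] + wm);
    }
  }
  return out;
}
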