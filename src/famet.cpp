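#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Non-local means denoising (Buades-style, pixelwise).
// For each pixel, patches inside the search window are compared by mean
// squared difference d2; window-centre pixels are averaged with weights
// exp(-max(d2 - 2*sigma^2, 0) / h^2). Patch/search sizes are odd widths.
// Borders use replicate padding. Fully deterministic.
//
// Implemented with one summed-area table of squared differences per
// search offset, so the cost is O(npixels * search^2), independent of
// the patch size.
// [[Rcpp::export(name = ".nlm_denoise_cpp")]]
NumericMatrix nlm_denoise_cpp(NumericMatrix img, int patch, int search,
                              double h, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  const int pr = patch / 2, sr = search / 2;
  const int pad = pr + sr;
  const int NR = nr + 2 * pad, NC = nc + 2 * pad;
  const double h2 = h * h;
  const double two_sigma2 = 2.0 * sigma * sigma;
  const double npatch = double(patch) * double(patch);

  // replicate-padded copy
  std::vector<double> P((size_t)NR * NC);
  for (int c = 0; c < NC; ++c) {
    int cc = c - pad; if (cc < 0) cc = 0; else if (cc >= nc) cc = nc - 1;
    for (int r = 0; r < NR; ++r) {
      int rr = r - pad; if (rr < 0) rr = 0; else if (rr >= nr) rr = nr - 1;
      P[(size_t)r + (size_t)c * NR] = img(rr, cc);
    }
  }

  std::vector<double> wsum((size_t)nr * nc, 0.0);
  std::vector<double> vsum((size_t)nr * nc, 0.0);
  // integral image of squared differences, with a zero top row/left col
  std::vector<double> S((size_t)(NR + 1) * (NC + 1), 0.0);

  for (int di = -sr; di <= sr; ++di) {
    for (int dj = -sr; dj <= sr; ++dj) {
      // squared-difference integral for this offset; the shifted pixel
      // is read from the padded copy (replicate semantics at borders)
      for (int c = 0; c < NC; ++c) {
        const int c2 = std::min(std::max(c + dj, 0), NC - 1);
        double colsum = 0.0;
        for (int r = 0; r < NR; ++r) {
          const int r2 = std::min(std::max(r + di, 0), NR - 1);
          const double d = P[(size_t)r + (size_t)c * NR] -
                           P[(size_t)r2 + (size_t)c2 * NR];
          colsum += d * d;
          S[(size_t)(r + 1) + (size_t)(c + 1) * (NR + 1)] =
            S[(size_t)(r + 1) + (size_t)c * (NR + 1)] + colsum;
        }
      }
      for (int j = 0; j < nc; ++j) {
        const int c0 = j + pad - pr, c1 = j + pad + pr + 1;
        for (int i = 0; i < nr; ++i) {
          const int r0 = i + pad - pr, r1 = i + pad + pr + 1;
          const double box =
            S[(size_t)r1 + (size_t)c1 * (NR + 1)] -
            S[(size_t)r0 + (size_t)c1 * (NR + 1)] -
            S[(size_t)r1 + (size_t)c0 * (NR + 1)] +
            S[(size_t)r0 + (size_t)c0 * (NR + 1)];
          double arg = box / npatch - two_sigma2;
          if (arg < 0.0) arg = 0.0;
          const double w = std::exp(-arg / h2);
          wsum[(size_t)i + (size_t)j * nr] += w;
          vsum[(size_t)i + (size_t)j * nr] +=
            w * P[(size_t)(i + pad + di) + (size_t)(j + pad + dj) * NR];
        }
      }
    }
  }

  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = vsum[(size_t)i + (size_t)j * nr] /
                  wsum[(size_t)i + (size_t)j * nr];
  return out;
}

// Connected-component labeling of a logical/0-1 matrix by breadth-first
// search with 4- or 8-connectivity. Labels are assigned in raster-scan
// discovery order starting at 1; background is 0.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);

  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[4] = {-1, 0, 0, 1};
  static const int dc4[4] = {0, -1, 1, 0};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = (connectivity == 8) ? 8 : 4;

  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int r = idx % nr, c = idx / nr;
        for (int k = 0; k < nn; ++k) {
          const int r2 = r + dr[k], c2 = c + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}
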