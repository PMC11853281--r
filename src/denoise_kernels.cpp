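#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Median by selection; for even n, mean of the two middle order statistics
// (same arithmetic as stats::median so kernel and oracle agree bitwise).
static double buf_median(std::vector<double> &v) {
  const size_t n = v.size();
  if (n == 0) return NA_REAL;
  const size_t h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    // long-double accumulation matches stats::median()'s mean() exactly
    m = static_cast<double>((static_cast<long double>(lo) +
                             static_cast<long double>(m)) / 2.0L);
  }
  return m;
}

// k x k median filter that honours the validity mask: each valid pixel is
// replaced by the median over valid pixels in its window (window clipped at
// the frame border); invalid pixels stay invalid and are reported as 0.
// A summed-area table of nonzero valid pixels lets windows that contain
// only zeros (the bulk of a denoised difference frame) return 0 at once.
// [[Rcpp::export]]
NumericMatrix cpp_masked_median_filter(NumericMatrix x, LogicalMatrix valid,
                                       int k) {
  const int nr = x.nrow(), nc = x.ncol(), h = k / 2;
  NumericMatrix out(nr, nc);
  // sat(i+1, j+1) = number of valid nonzero pixels in x[0..i, 0..j]
  std::vector<int> sat((nr + 1) * (nc + 1), 0);
  for (int j = 0; j < nc; j++) {
    int colsum = 0;
    for (int i = 0; i < nr; i++) {
      if (valid(i, j) && x(i, j) != 0.0) colsum++;
      sat[(i + 1) + (j + 1) * (nr + 1)] = sat[(i + 1) + j * (nr + 1)] + colsum;
    }
  }
  std::vector<double> buf;
  buf.reserve(k * k);
  for (int j = 0; j < nc; j++) {
    const int j0 = std::max(0, j - h), j1 = std::min(nc - 1, j + h);
    for (int i = 0; i < nr; i++) {
      if (!valid(i, j)) { out(i, j) = 0.0; continue; }
      const int i0 = std::max(0, i - h), i1 = std::min(nr - 1, i + h);
      const int nnz = sat[(i1 + 1) + (j1 + 1) * (nr + 1)]
                    - sat[i0 + (j1 + 1) * (nr + 1)]
                    - sat[(i1 + 1) + j0 * (nr + 1)]
                    + sat[i0 + j0 * (nr + 1)];
      if (nnz == 0) { out(i, j) = 0.0; continue; }
      buf.clear();
      for (int jj = j0; jj <= j1; jj++)
        for (int ii = i0; ii <= i1; ii++)
          if (valid(ii, jj)) buf.push_back(x(ii, jj));
      out(i, j) = buf_median(buf); // centre pixel is valid, so never empty
    }
  }
  return out;
}

// Fused per-span temporal median: takes the contributing frames directly
// and applies the invalid-pixel convention (0 or outside [lo, hi]) while
// collecting values, avoiding intermediate masked copies in R.
// [[Rcpp::export]]
NumericVector cpp_span_median(List frames, double lo, double hi) {
  const int nf = frames.size();
  std::vector<NumericMatrix> ms;
  ms.reserve(nf);
  for (int j = 0; j < nf; j++) ms.push_back(as<NumericMatrix>(frames[j]));
  const int np = ms[0].size();
  NumericVector out(np);
  std::vector<double> buf;
  buf.reserve(nf);
  for (int i = 0; i < np; i++) {
    buf.clear();
    for (int j = 0; j < nf; j++) {
      const double v = ms[j][i];
      if (v > 0 && v >= lo && v <= hi) buf.push_back(v);
    }
    const int ninv = nf - static_cast<int>(buf.size());
    out[i] = (2 * ninv > nf) ? 0.0 : buf_median(buf);
  }
  return out;
}

// Connected-component labelling of active pixels (4- or 8-connectivity),
// labels 1..K in scan order, 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix active, int connectivity) {
  const int nr = active.nrow(), nc = active.ncol();
  IntegerMatrix lab(nr, nc);
  const int ndir = (connectivity == 8) ? 8 : 4;
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int cur = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      if (!active(i, j) || lab(i, j)) continue;
      cur++;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = cur;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % nr, pj = p / nr;
        for (int d = 0; d < ndir; d++) {
          const int qi = pi + dr[d], qj = pj + dc[d];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (active(qi, qj) && !lab(qi, qj)) {
            lab(qi, qj) = cur;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}
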