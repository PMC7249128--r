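#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Median filter with replicated borders. Values are arbitrary integers
// (16-bit depth units in practice); kernel must be odd.
// [[Rcpp::export(name = ".cpp_median_filter")]]
IntegerMatrix cpp_median_filter(const IntegerMatrix& x, int kernel) {
  const int nr = x.nrow(), nc = x.ncol();
  const int h = kernel / 2;
  IntegerMatrix out(nr, nc);
  std::vector<int> buf;
  buf.reserve(kernel * kernel);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int dj = -h; dj <= h; ++dj) {
        int cj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = -h; di <= h; ++di) {
          int ci = std::min(std::max(i + di, 0), nr - 1);
          buf.push_back(x(ci, cj));
        }
      }
      std::nth_element(buf.begin(), buf.begin() + buf.size() / 2, buf.end());
      out(i, j) = buf[buf.size() / 2];
    }
  }
  return out;
}

// Fixed-range flood fill: each candidate pixel is compared against the
// intensity of the ORIGINAL seed of its component (not its neighbour).
// Seeds are 1-based (row, col) pairs, processed in order; a seed landing on
// an already-filled pixel is skipped without flooding.
// [[Rcpp::export(name = ".cpp_flood_fill")]]
List cpp_flood_fill(const IntegerMatrix& gray, const IntegerMatrix& seeds,
                    int lowdiff, int updiff, int connectivity) {
  const int nr = gray.nrow(), nc = gray.ncol();
  IntegerMatrix mask(nr, nc);
  const int n_off = (connectivity == 8) ? 8 : 4;
  const int off_r[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int off_c[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int flooded = 0;
  std::vector<int> queue;
  for (int s = 0; s < seeds.nrow(); ++s) {
    const int sr = seeds(s, 0) - 1, sc = seeds(s, 1) - 1;
    if (sr < 0 || sr >= nr || sc < 0 || sc >= nc)
      stop("seed out of bounds");
    if (mask(sr, sc) == 1) continue;
    ++flooded;
    const int ref = gray(sr, sc);
    const int lo = ref - lowdiff, hi = ref + updiff;
    mask(sr, sc) = 1;
    queue.clear();
    queue.push_back(sr + sc * nr);
    while (!queue.empty()) {
      const int p = queue.back();
      queue.pop_back();
      const int pr = p % nr, pc = p / nr;
      for (int k = 0; k < n_off; ++k) {
        const int qr = pr + off_r[k], qc = pc + off_c[k];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        if (mask(qr, qc) == 1) continue;
        const int v = gray(qr, qc);
        if (v >= lo && v <= hi) {
          mask(qr, qc) = 1;
          queue.push_back(qr + qc * nr);
        }
      }
    }
  }
  return List::create(_["mask"] = mask, _["seeds_flooded"] = flooded);
}

// Connected-component labelling of a binary mask; labels assigned in
// column-major scan order starting at 1.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int n_off = (connectivity == 4) ? 4 : 8;
  const int off_r[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int off_c[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int next = 0;
  std::vector<int> queue;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      queue.clear();
      queue.push_back(i + j * nr);
      while (!queue.empty()) {
        const int p = queue.back();
        queue.pop_back();
        const int pr = p % nr, pc = p / nr;
        for (int k = 0; k < n_off; ++k) {
          const int qr = pr + off_r[k], qc = pc + off_c[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (mask(qr, qc) == 0 || lab(qr, qc) != 0) continue;
          lab(qr, qc) = next;
          queue.push_back(qr + qc * nr);
        }
      }
    }
  }
  return lab;
}
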