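#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Bilinear interpolation of m at fractional (row, col) with periodic wrap.
static inline double bilin_periodic(const NumericMatrix& m, double r, double c) {
  const int nr = m.nrow(), nc = m.ncol();
  double rw = r - nr * std::floor(r / nr);
  double cw = c - nc * std::floor(c / nc);
  int r0 = (int)std::floor(rw), c0 = (int)std::floor(cw);
  if (r0 >= nr) r0 = 0;
  if (c0 >= nc) c0 = 0;
  const int r1 = (r0 + 1 == nr) ? 0 : r0 + 1;
  const int c1 = (c0 + 1 == nc) ? 0 : c0 + 1;
  const double fr = rw - r0, fc = cw - c0;
  return m(r0, c0) * (1 - fr) * (1 - fc) + m(r1, c0) * fr * (1 - fc) +
         m(r0, c1) * (1 - fr) * fc + m(r1, c1) * fr * fc;
}

// Directional local-maximum test: a pixel is a WTMM point iff its modulus is
// >= the bilinearly interpolated modulus one pixel away along +/- the gradient
// direction, with strict inequality on at least one side (keeps single-pixel
// ridges on discrete plateaus, drops exactly flat regions).
// Angle convention: x = column increasing rightward, y = row increasing
// downward, angle measured from +x toward +y.
// [[Rcpp::export]]
LogicalMatrix wtmm_detect_cpp(NumericMatrix modulus, NumericMatrix argument) {
  const int nr = modulus.nrow(), nc = modulus.ncol();
  LogicalMatrix keep(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      const double m = modulus(i, j);
      if (!(m > 0)) continue;
      const double a = argument(i, j);
      const double dr = std::sin(a), dc = std::cos(a);
      const double mp = bilin_periodic(modulus, i + dr, j + dc);
      const double mm = bilin_periodic(modulus, i - dr, j - dc);
      if (m >= mp && m >= mm && (m > mp || m > mm)) keep(i, j) = true;
    }
  }
  return keep;
}

// Label 8-connected components of a logical mask by breadth-first traversal.
// Returns 1-based linear indices in visit order, the component id of each
// visited pixel, and the label raster. wrap = TRUE joins components across
// the periodic image boundary.
// [[Rcpp::export]]
List label_chains_cpp(LogicalMatrix mask, bool wrap) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix label(nr, nc);
  std::vector<int> order_idx, order_lab;
  order_idx.reserve(nr * nc / 8 + 1);
  order_lab.reserve(nr * nc / 8 + 1);
  int next_label = 0;
  std::vector<int> queue;
  for (int j0 = 0; j0 < nc; ++j0) {
    for (int i0 = 0; i0 < nr; ++i0) {
      if (!mask(i0, j0) || label(i0, j0) != 0) continue;
      ++next_label;
      queue.clear();
      queue.push_back(i0 + j0 * nr);
      label(i0, j0) = next_label;
      size_t head = 0;
      while (head < queue.size()) {
        const int lin = queue[head++];
        const int i = lin % nr, j = lin / nr;
        order_idx.push_back(lin + 1);
        order_lab.push_back(next_label);
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ii = i + di, jj = j + dj;
            if (wrap) {
              if (ii < 0) ii += nr; else if (ii >= nr) ii -= nr;
              if (jj < 0) jj += nc; else if (jj >= nc) jj -= nc;
            } else if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) {
              continue;
            }
            if (mask(ii, jj) && label(ii, jj) == 0) {
              label(ii, jj) = next_label;
              queue.push_back(ii + jj * nr);
            }
          }
        }
      }
    }
  }
  return List::create(_["label"] = label,
                      _["idx"] = IntegerVector(order_idx.begin(), order_idx.end()),
                      _["chain"] = IntegerVector(order_lab.begin(), order_lab.end()),
                      _["n_chains"] = next_label);
}
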