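#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Stack-based flood fill over a column-major char grid.
// Marks the component containing `start` in `seen` and returns nothing.
static void flood(const std::vector<char>& px, std::vector<char>& seen,
                  std::vector<int>& stack, int start, int nr, int nc, int conn) {
  static const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  static const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (conn == 8) ? 8 : 4; // first 4 offsets are the 4-neighbourhood
  seen[start] = 1;
  stack.clear();
  stack.push_back(start);
  while (!stack.empty()) {
    const int cur = stack.back();
    stack.pop_back();
    const int ci = cur % nr, cj = cur / nr;
    for (int k = 0; k < nn; ++k) {
      const int ni = ci + dr8[k], nj = cj + dc8[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      const int nidx = ni + nj * nr;
      if (px[nidx] && !seen[nidx]) {
        seen[nidx] = 1;
        stack.push_back(nidx);
      }
    }
  }
}

static int n_components(const std::vector<char>& px, int nr, int nc, int conn) {
  std::vector<char> seen(px.size(), 0);
  std::vector<int> stack;
  int count = 0;
  for (int idx = 0; idx < nr * nc; ++idx) {
    if (px[idx] && !seen[idx]) {
      ++count;
      flood(px, seen, stack, idx, nr, nc, conn);
    }
  }
  return count;
}

// b0: foreground components, 8-connected.
// b1: background components, 4-connected, that cannot reach the image border
//     (equivalently: holes after padding with one background ring).
static void betti_pair(const std::vector<char>& fg, int nr, int nc,
                       int& b0, int& b1) {
  b0 = n_components(fg, nr, nc, 8);
  std::vector<char> bg(fg.size());
  for (size_t i = 0; i < fg.size(); ++i) bg[i] = fg[i] ? 0 : 1;
  // flood the border-connected background first, then count what remains
  std::vector<char> seen(bg.size(), 0);
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (i != 0 && i != nr - 1 && j != 0 && j != nc - 1) continue;
      const int idx = i + j * nr;
      if (bg[idx] && !seen[idx]) flood(bg, seen, stack, idx, nr, nc, 4);
    }
  }
  b1 = 0;
  for (int idx = 0; idx < nr * nc; ++idx) {
    if (bg[idx] && !seen[idx]) {
      ++b1;
      flood(bg, seen, stack, idx, nr, nc, 4);
    }
  }
}

static std::vector<char> as_grid(const LogicalMatrix& img) {
  std::vector<char> px(img.size());
  for (int i = 0; i < img.size(); ++i) px[i] = (img[i] == TRUE) ? 1 : 0;
  return px;
}

// [[Rcpp::export(name = ".cpp_count_components")]]
int cpp_count_components(LogicalMatrix img, int connectivity) {
  return n_components(as_grid(img), img.nrow(), img.ncol(), connectivity);
}

// [[Rcpp::export(name = ".cpp_betti")]]
IntegerVector cpp_betti(LogicalMatrix img) {
  int b0, b1;
  betti_pair(as_grid(img), img.nrow(), img.ncol(), b0, b1);
  return IntegerVector::create(_["b0"] = b0, _["b1"] = b1);
}

// Sublevel-set sweep: b1 of {mask & intensity <= t} for every t in 0..255.
// [[Rcpp::export(name = ".cpp_b1_curve")]]
IntegerVector cpp_b1_curve(IntegerMatrix intensity, LogicalMatrix mask) {
  const int nr = intensity.nrow(), nc = intensity.ncol();
  IntegerVector curve(256);
  std::vector<char> fg(static_cast<size_t>(nr) * nc);
  for (int t = 0; t < 256; ++t) {
    for (int i = 0; i < nr * nc; ++i)
      fg[i] = (mask[i] == TRUE && intensity[i] <= t) ? 1 : 0;
    int b0, b1;
    betti_pair(fg, nr, nc, b0, b1);
    curve[t] = b1;
  }
  return curve;
}
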