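#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 8-connected component labeling of a binary image by iterative flood fill.
// Labels are assigned in column-major scan order, so the component containing
// the earliest pixel in scan order gets the smallest label.
// [[Rcpp::export(name = ".cc_label8")]]
IntegerMatrix cc_label8(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (mask(qi, qj) && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Binary dilation by a kh x kw all-ones structuring element.
// The offset set runs over all (di, dj) with 0 <= di < kh, 0 <= dj < kw,
// shifted so the element is as centered as possible (floor((k-1)/2)).
// Pixels outside the image are background.
static LogicalMatrix dilate_box(const LogicalMatrix& m, int kh, int kw,
                                int oi, int oj) {
  int nr = m.nrow(), nc = m.ncol();
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!m(i, j)) continue;
      for (int dj = 0; dj < kw; ++dj)
        for (int di = 0; di < kh; ++di) {
          int qi = i + di - oi, qj = j + dj - oj;
          if (qi >= 0 && qi < nr && qj >= 0 && qj < nc) out(qi, qj) = true;
        }
    }
  return out;
}

// Erosion paired with dilate_box: a pixel survives iff every offset lands on
// foreground.  `pad_fg` treats out-of-bounds pixels as foreground, which is
// what the dilation/erosion pair of a morphological closing requires so that
// closing is extensive (output always contains the input).
static LogicalMatrix erode_box(const LogicalMatrix& m, int kh, int kw,
                               int oi, int oj, bool pad_fg) {
  int nr = m.nrow(), nc = m.ncol();
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      bool keep = true;
      for (int dj = 0; dj < kw && keep; ++dj)
        for (int di = 0; di < kh && keep; ++di) {
          int qi = i + di - oi, qj = j + dj - oj;
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) {
            if (!pad_fg) keep = false;
          } else if (!m(qi, qj)) keep = false;
        }
      out(i, j) = keep;
    }
  return out;
}

// [[Rcpp::export(name = ".binary_dilate")]]
LogicalMatrix binary_dilate(const LogicalMatrix& mask, int size) {
  int o = (size - 1) / 2;
  return dilate_box(mask, size, size, o, o);
}

// Morphological closing with a size x size square: dilation followed by the
// paired erosion computed on a sufficiently padded domain (background pad for
// the dilation, so the pair is exact and extensivity holds at the borders).
// [[Rcpp::export(name = ".binary_close")]]
LogicalMatrix binary_close(const LogicalMatrix& mask, int size) {
  int nr = mask.nrow(), nc = mask.ncol(), k = size;
  LogicalMatrix pad(nr + 2 * k, nc + 2 * k);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      pad(i + k, j + k) = mask(i, j);
  int o = (k - 1) / 2;
  LogicalMatrix d = dilate_box(pad, k, k, o, o);
  LogicalMatrix e = erode_box(d, k, k, o, o, false);
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = e(i + k, j + k);
  return out;
}

// Moore-neighbor boundary trace (8-connected, clockwise) of the component
// containing the earliest foreground pixel in column-major scan order.
// Returns an n x 2 matrix of 1-based (row, col) pixels.  Terminates when the
// first transition (start pixel -> first move direction) repeats, which is
// robust on one-pixel-wide spurs.
// [[Rcpp::export(name = ".trace_boundary")]]
IntegerMatrix trace_boundary(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  int si = -1, sj = -1;
  for (int j = 0; j < nc && si < 0; ++j)
    for (int i = 0; i < nr; ++i)
      if (mask(i, j)) { si = i; sj = j; break; }
  if (si < 0) return IntegerMatrix(0, 2);
  // clockwise Moore neighborhood starting from "up" (image coordinates:
  // row grows downward, col grows rightward)
  const int di[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dj[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  std::vector<int> ri, rj;
  ri.push_back(si); rj.push_back(sj);
  // backtrack: the scan arrives from above (previous row), direction index 0
  int ci = si, cj = sj, back = 0, first_move = -1;
  for (int guard = 0; guard < 8 * nr * nc + 8; ++guard) {
    int found = -1;
    for (int s = 1; s <= 8; ++s) {
      int d = (back + s) % 8;
      int qi = ci + di[d], qj = cj + dj[d];
      if (qi >= 0 && qi < nr && qj >= 0 && qj < nc && mask(qi, qj)) {
        found = d; break;
      }
    }
    if (found < 0) break;  // isolated pixel
    bool at_start = (ci == si && cj == sj);
    if (at_start) {
      if (first_move < 0) first_move = found;
      else if (found == first_move) break;  // closed the loop
    }
    ci += di[found]; cj += dj[found];
    back = (found + 4) % 8;
    if (!(ci == si && cj == sj)) { ri.push_back(ci); rj.push_back(cj); }
  }
  IntegerMatrix out(ri.size(), 2);
  for (size_t k = 0; k < ri.size(); ++k) {
    out(k, 0) = ri[k] + 1;
    out(k, 1) = rj[k] + 1;
  }
  return out;
}
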