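#include <Rcpp.h>
#include <map>
#include <vector>
#include <utility>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Connected-component labeling of same-class cells. Patch ids are assigned in
// row-major first-contact order (row 1 left to right, then row 2, ...) so that
// patch tables are reproducible across runs. nodata cells are never labeled.
// [[Rcpp::export]]
List label_patches_cpp(const IntegerMatrix& cells, int nodata, int connectivity) {
  const int nr = cells.nrow(), nc = cells.ncol();
  IntegerMatrix labels(nr, nc);
  std::vector<int> patch_class;
  std::vector<int> stack;
  stack.reserve(1024);

  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  const int nd = (connectivity == 8) ? 8 : 4;

  int next = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      const int v = cells(r, c);
      if (v == nodata || labels(r, c) != 0) continue;
      ++next;
      patch_class.push_back(v);
      labels(r, c) = next;
      stack.push_back(r * nc + c);
      while (!stack.empty()) {
        const int cur = stack.back();
        stack.pop_back();
        const int cr = cur / nc, cc = cur % nc;
        for (int k = 0; k < nd; ++k) {
          const int r2 = cr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (labels(r2, c2) == 0 && cells(r2, c2) == v) {
            labels(r2, c2) = next;
            stack.push_back(r2 * nc + c2);
          }
        }
      }
    }
  }
  return List::create(_["labels"] = labels,
                      _["patch_class"] = wrap(patch_class));
}

// Per-patch cell counts and exposed side counts, split by side length:
// sides_w are horizontal sides (exposures to the cell above/below), each of
// length cell_width; sides_h are vertical sides (exposures left/right), each
// of length cell_height. A side is exposed when the rook neighbour carries a
// different label (different class, nodata, or off-raster).
// [[Rcpp::export]]
List patch_stats_cpp(const IntegerMatrix& labels, int n_patches) {
  const int nr = labels.nrow(), nc = labels.ncol();
  IntegerVector n_cells(n_patches), sides_w(n_patches), sides_h(n_patches);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      const int L = labels(r, c);
      if (L == 0) continue;
      const int i = L - 1;
      ++n_cells[i];
      if (r == 0 || labels(r - 1, c) != L) ++sides_w[i];
      if (r == nr - 1 || labels(r + 1, c) != L) ++sides_w[i];
      if (c == 0 || labels(r, c - 1) != L) ++sides_h[i];
      if (c == nc - 1 || labels(r, c + 1) != L) ++sides_h[i];
    }
  }
  return List::create(_["n_cells"] = n_cells,
                      _["sides_w"] = sides_w,
                      _["sides_h"] = sides_h);
}

// Single pass over the lattice counting every interior shared cell side once
// per unordered cell pair (rook rule). `idx` holds 1-based class indices with
// nodata recoded as its own pseudo-class. Horizontal neighbour pairs
// (r,c)-(r,c+1) share a vertical side of length cell_height; vertical pairs
// (r,c)-(r+1,c) share a horizontal side of length cell_width. Raster-border
// sides are tallied per class, split the same way.
// [[Rcpp::export]]
List adjacency_cpp(const IntegerMatrix& idx, int m) {
  const int nr = idx.nrow(), nc = idx.ncol();
  NumericMatrix e_horiz(m, m), e_vert(m, m);
  NumericVector border_w(m), border_h(m);

  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c + 1 < nc; ++c) {
      const int a = idx(r, c) - 1, b = idx(r, c + 1) - 1;
      e_horiz(a, b) += 1.0;
      if (a != b) e_horiz(b, a) += 1.0;
    }
  }
  for (int r = 0; r + 1 < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      const int a = idx(r, c) - 1, b = idx(r + 1, c) - 1;
      e_vert(a, b) += 1.0;
      if (a != b) e_vert(b, a) += 1.0;
    }
  }
  for (int c = 0; c < nc; ++c) {
    border_w[idx(0, c) - 1] += 1.0;
    border_w[idx(nr - 1, c) - 1] += 1.0;
  }
  for (int r = 0; r < nr; ++r) {
    border_h[idx(r, 0) - 1] += 1.0;
    border_h[idx(r, nc - 1) - 1] += 1.0;
  }
  return List::create(_["e_horiz"] = e_horiz, _["e_vert"] = e_vert,
                      _["border_w"] = border_w, _["border_h"] = border_h);
}

// Euclidean nearest-neighbour distance per patch: the minimum cell-center to
// cell-center distance to any other patch of the same class. Only boundary
// cells (cells with a rook neighbour outside the patch, or on the raster
// edge) are compared; the minimum inter-patch distance is always attained at
// boundary cells, so this equals the all-pairs brute force. Single-patch
// classes get NaN (undefined, not zero).
// [[Rcpp::export]]
NumericVector patch_enn_cpp(const IntegerMatrix& labels,
                            const IntegerVector& patch_class,
                            double cell_width, double cell_height) {
  const int nr = labels.nrow(), nc = labels.ncol();
  const int K = patch_class.size();
  std::vector<std::vector<std::pair<int, int> > > bcells(K);

  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      const int L = labels(r, c);
      if (L == 0) continue;
      const bool boundary =
        (r == 0 || labels(r - 1, c) != L) || (r == nr - 1 || labels(r + 1, c) != L) ||
        (c == 0 || labels(r, c - 1) != L) || (c == nc - 1 || labels(r, c + 1) != L);
      if (boundary) bcells[L - 1].push_back(std::make_pair(r, c));
    }
  }

  std::map<int, std::vector<int> > by_class;
  for (int k = 0; k < K; ++k) by_class[patch_class[k]].push_back(k);

  NumericVector enn(K, R_NaN);
  const double inf = std::numeric_limits<double>::infinity();

  for (std::map<int, std::vector<int> >::const_iterator it = by_class.begin();
       it != by_class.end(); ++it) {
    const std::vector<int>& grp = it->second;
    const int G = grp.size();
    if (G < 2) continue;
    std::vector<double> best(G, inf);
    for (int i = 0; i < G; ++i) {
      const std::vector<std::pair<int, int> >& A = bcells[grp[i]];
      for (int j = i + 1; j < G; ++j) {
        const std::vector<std::pair<int, int> >& B = bcells[grp[j]];
        double d2min = inf;
        for (size_t a = 0; a < A.size(); ++a) {
          for (size_t b = 0; b < B.size(); ++b) {
            const double dx = (A[a].second - B[b].second) * cell_width;
            const double dy = (A[a].first - B[b].first) * cell_height;
            const double d2 = dx * dx + dy * dy;
            if (d2 < d2min) d2min = d2;
          }
        }
        if (d2min < best[i]) best[i] = d2min;
        if (d2min < best[j]) best[j] = d2min;
      }
    }
    for (int i = 0; i < G; ++i) enn[grp[i]] = std::sqrt(best[i]);
  }
  return enn;
}
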