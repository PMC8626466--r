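#include <Rcpp.h>
using namespace Rcpp;

// Bilinear sampling of image rows at fractional global positions.
// Positions are 0-based: (x = 0, y = 0) is the centre of img(1, 1).
// out(r, c) = img interpolated at (y = row_y[r], x = row_x[r] + c - 1).
// Out-of-canvas samples return NA.
// [[Rcpp::export]]
NumericMatrix cpp_sample_rows(NumericMatrix img, NumericVector row_x,
                              NumericVector row_y, int ncol_out) {
  int H = img.nrow(), W = img.ncol();
  int nr = row_y.size();
  NumericMatrix out(nr, ncol_out);
  for (int r = 0; r < nr; ++r) {
    double y = row_y[r];
    int y0 = (int)std::floor(y);
    double fy = y - y0;
    for (int c = 0; c < ncol_out; ++c) {
      double x = row_x[r] + c;
      int x0 = (int)std::floor(x);
      double fx = x - x0;
      if (y0 < 0 || y0 + 1 >= H || x0 < 0 || x0 + 1 >= W) {
        // exact-edge case: allow y == H-1 / x == W-1 with zero fraction
        bool ok = (y0 >= 0 && x0 >= 0 &&
                   (y0 + 1 < H || (y0 == H - 1 && fy == 0.0)) &&
                   (x0 + 1 < W || (x0 == W - 1 && fx == 0.0)));
        if (!ok) { out(r, c) = NA_REAL; continue; }
      }
      double v00 = img(y0, x0);
      double v01 = (fx > 0.0) ? img(y0, x0 + 1) : v00;
      double v10 = (fy > 0.0) ? img(y0 + 1, x0) : v00;
      double v11 = (fx > 0.0 && fy > 0.0) ? img(y0 + 1, x0 + 1) : v10;
      out(r, c) = (1 - fy) * ((1 - fx) * v00 + fx * v01) +
                  fy * ((1 - fx) * v10 + fx * v11);
    }
  }
  return out;
}

// Accumulate one frame into mosaic accumulators by bilinear splatting.
// acc/wacc are modified in place; row_x/row_y are 0-based positions of each
// source row's first pixel in mosaic coordinates.
// [[Rcpp::export]]
void cpp_splat_frame(NumericMatrix acc, NumericMatrix wacc,
                     NumericMatrix img, NumericMatrix w,
                     NumericVector row_x, NumericVector row_y) {
  int H = acc.nrow(), W = acc.ncol();
  int fr = img.nrow(), fc = img.ncol();
  for (int r = 0; r < fr; ++r) {
    double y = row_y[r];
    int y0 = (int)std::floor(y);
    double fy = y - y0;
    for (int c = 0; c < fc; ++c) {
      double x = row_x[r] + c;
      int x0 = (int)std::floor(x);
      double fx = x - x0;
      double v = img(r, c), wt = w(r, c);
      double ww[4] = {(1 - fy) * (1 - fx), (1 - fy) * fx,
                      fy * (1 - fx), fy * fx};
      int ys[4] = {y0, y0, y0 + 1, y0 + 1};
      int xs[4] = {x0, x0 + 1, x0, x0 + 1};
      for (int k = 0; k < 4; ++k) {
        if (ww[k] <= 0.0) continue;
        if (ys[k] < 0 || ys[k] >= H || xs[k] < 0 || xs[k] >= W) continue;
        acc(ys[k], xs[k]) += v * wt * ww[k];
        wacc(ys[k], xs[k]) += wt * ww[k];
      }
    }
  }
}

// Inverse-warp (gather) accumulation of one frame into mosaic
// accumulators: for every mosaic pixel covered by the frame, the frame is
// sampled bilinearly at the exact inverse position, avoiding the extra
// blur a forward splat would introduce. Row r of the frame lies at global
// y = row_y[r] (one y per row; rows stay horizontal) spanning
// x in [row_x[r], row_x[r] + W).
// [[Rcpp::export]]
void cpp_gather_frame(NumericMatrix acc, NumericMatrix wacc,
                      NumericMatrix img, NumericMatrix w,
                      NumericVector row_x, NumericVector row_y) {
  int H = acc.nrow(), Wc = acc.ncol();
  int fr = img.nrow(), fc = img.ncol();
  // row_y is monotone increasing up to small drift; for each output row Y
  // find the fractional source row by scanning (row_y[r] ~ r + const)
  double ymin = row_y[0], ymax = row_y[fr - 1];
  int Y0 = std::max(0, (int)std::ceil(ymin));
  int Y1 = std::min(H - 1, (int)std::floor(ymax));
  for (int Y = Y0; Y <= Y1; ++Y) {
    // locate r with row_y[r] <= Y <= row_y[r+1]
    int r = std::min(std::max((int)(Y - ymin), 0), fr - 2);
    while (r > 0 && row_y[r] > Y) --r;
    while (r < fr - 2 && row_y[r + 1] < Y) ++r;
    if (row_y[r] > Y || row_y[r + 1] < Y) continue;
    double denom = row_y[r + 1] - row_y[r];
    double fy = denom > 1e-12 ? (Y - row_y[r]) / denom : 0.0;
    double xr = (1 - fy) * row_x[r] + fy * row_x[r + 1];
    int X0 = std::max(0, (int)std::ceil(xr));
    int X1 = std::min(Wc - 1, (int)std::floor(xr + fc - 1));
    for (int X = X0; X <= X1; ++X) {
      double cs = X - xr;
      int c0 = (int)std::floor(cs);
      double fx = cs - c0;
      if (c0 < 0 || c0 >= fc) continue;
      int c1 = std::min(c0 + 1, fc - 1);
      double v = (1 - fy) * ((1 - fx) * img(r, c0) + fx * img(r, c1)) +
                 fy * ((1 - fx) * img(r + 1, c0) + fx * img(r + 1, c1));
      double wt = (1 - fy) * ((1 - fx) * w(r, c0) + fx * w(r, c1)) +
                  fy * ((1 - fx) * w(r + 1, c0) + fx * w(r + 1, c1));
      acc(Y, X) += v * wt;
      wacc(Y, X) += wt;
    }
  }
}

static inline int nb(const IntegerMatrix &m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c) ? 1 : 0;
}

// Sequential removal of 8-simple pixels: a set pixel with >= 2 neighbours
// whose set neighbours form a single 8-connected cluster is redundant
// (staircase artifact of Zhang-Suen on diagonals) and is removed.
static void prune_simple(IntegerMatrix &m, int max_sweeps = 2) {
  int H = m.nrow(), W = m.ncol();
  bool changed = true;
  int sweep = 0;
  // bounded sweeps: unbounded repetition can cascade along two-pixel-wide
  // diagonal ribbons and erode entire limbs
  while (changed && sweep++ < max_sweeps) {
    changed = false;
    for (int r = 0; r < H; ++r) {
      for (int c = 0; c < W; ++c) {
        if (!m(r, c)) continue;
        int rr[8], cc[8], n = 0;
        for (int dr = -1; dr <= 1; ++dr)
          for (int dc = -1; dc <= 1; ++dc) {
            if (!dr && !dc) continue;
            int r2 = r + dr, c2 = c + dc;
            if (r2 < 0 || c2 < 0 || r2 >= H || c2 >= W) continue;
            if (m(r2, c2)) { rr[n] = r2; cc[n] = c2; ++n; }
          }
        if (n < 2) continue;
        // BFS over the neighbour set, adjacency = Chebyshev distance <= 1
        bool vis[8] = {false};
        int stack[8], top = 0;
        stack[top++] = 0; vis[0] = true;
        int seen = 1;
        while (top) {
          int k = stack[--top];
          for (int j = 0; j < 8 && j < n; ++j) {
            if (vis[j]) continue;
            if (std::abs(rr[j] - rr[k]) <= 1 && std::abs(cc[j] - cc[k]) <= 1) {
              vis[j] = true; stack[top++] = j; ++seen;
            }
          }
        }
        if (seen == n) { m(r, c) = 0; changed = true; }
      }
    }
  }
}

// Zhang-Suen thinning of a binary mask to a 1-px-wide 8-connected skeleton.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  IntegerMatrix m = clone(mask);
  int H = m.nrow(), W = m.ncol();
  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int r = 0; r < H; ++r) {
        for (int c = 0; c < W; ++c) {
          if (!m(r, c)) continue;
          // neighbours P2..P9 clockwise from north
          int p[8] = {nb(m, r - 1, c),     nb(m, r - 1, c + 1),
                      nb(m, r, c + 1),     nb(m, r + 1, c + 1),
                      nb(m, r + 1, c),     nb(m, r + 1, c - 1),
                      nb(m, r, c - 1),     nb(m, r - 1, c - 1)};
          int B = 0, A = 0;
          for (int k = 0; k < 8; ++k) {
            B += p[k];
            if (p[k] == 0 && p[(k + 1) % 8] == 1) ++A;
          }
          if (B < 2 || B > 6 || A != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k)
        m(kill[k].first, kill[k].second) = 0;
    }
  }
  prune_simple(m);
  return m;
}
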