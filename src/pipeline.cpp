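#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Symmetric (edge-including) reflection of an out-of-range index.
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Pad a matrix by `pad` pixels on every side with symmetric reflection.
static NumericMatrix pad_reflect(const NumericMatrix& img, int pad) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr + 2 * pad, nc + 2 * pad);
  for (int r = 0; r < nr + 2 * pad; ++r) {
    int rs = reflect_idx(r - pad, nr);
    for (int c = 0; c < nc + 2 * pad; ++c) {
      out(r, c) = img(rs, reflect_idx(c - pad, nc));
    }
  }
  return out;
}

// Non-local means. Patch dissimilarity is the mean squared intensity
// difference over aligned (2*patch_radius+1)^2 patches; the weight is
// exp(-d2 / h^2). The centre pixel participates with weight 1 and weights
// are normalised to sum to 1, so the output is a convex combination of
// input intensities. Borders are handled by mirror reflection.
// [[Rcpp::export]]
NumericMatrix cpp_nlm(NumericMatrix img, int patch_radius, int search_radius,
                      double h) {
  int nr = img.nrow(), nc = img.ncol();
  int pad = search_radius + patch_radius;
  NumericMatrix P = pad_reflect(img, pad);
  NumericMatrix out(nr, nc);
  int ps = 2 * patch_radius + 1;
  double npatch = (double)(ps * ps);
  double inv_h2 = 1.0 / (h * h);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int pr = r + pad, pc = c + pad;  // centre in padded coords
      double wsum = 0.0, vsum = 0.0;
      for (int dr = -search_radius; dr <= search_radius; ++dr) {
        for (int dc = -search_radius; dc <= search_radius; ++dc) {
          double d2 = 0.0;
          for (int i = -patch_radius; i <= patch_radius; ++i) {
            for (int j = -patch_radius; j <= patch_radius; ++j) {
              double a = P(pr + i, pc + j);
              double b = P(pr + dr + i, pc + dc + j);
              double d = a - b;
              d2 += d * d;
            }
          }
          double w = std::exp(-(d2 / npatch) * inv_h2);
          wsum += w;
          vsum += w * P(pr + dr, pc + dc);
        }
      }
      out(r, c) = vsum / wsum;
    }
  }
  return out;
}

// Local mean and (population) standard deviation over a square window of
// radius `radius`, mirror-reflected at the borders. Uses integral images
// over the padded matrix.
// [[Rcpp::export]]
List cpp_local_mean_sd(NumericMatrix img, int radius) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix P = pad_reflect(img, radius);
  int pr = P.nrow(), pc = P.ncol();
  // integral images with a leading zero row/column
  std::vector<double> S((pr + 1) * (pc + 1), 0.0);
  std::vector<double> S2((pr + 1) * (pc + 1), 0.0);
  int W = pc + 1;
  for (int r = 1; r <= pr; ++r) {
    for (int c = 1; c <= pc; ++c) {
      double v = P(r - 1, c - 1);
      S[r * W + c]  = v     + S[(r - 1) * W + c] + S[r * W + c - 1] - S[(r - 1) * W + c - 1];
      S2[r * W + c] = v * v + S2[(r - 1) * W + c] + S2[r * W + c - 1] - S2[(r - 1) * W + c - 1];
    }
  }
  NumericMatrix mu(nr, nc), sd(nr, nc);
  double nwin = (double)((2 * radius + 1) * (2 * radius + 1));
  for (int r = 0; r < nr; ++r) {
    int r0 = r, r1 = r + 2 * radius + 1;  // rows in padded coords [r0, r1)
    for (int c = 0; c < nc; ++c) {
      int c0 = c, c1 = c + 2 * radius + 1;
      double s  = S[r1 * W + c1] - S[r0 * W + c1] - S[r1 * W + c0] + S[r0 * W + c0];
      double s2 = S2[r1 * W + c1] - S2[r0 * W + c1] - S2[r1 * W + c0] + S2[r0 * W + c0];
      double m = s / nwin;
      double v = s2 / nwin - m * m;
      if (v < 0) v = 0;
      mu(r, c) = m;
      sd(r, c) = std::sqrt(v);
    }
  }
  return List::create(_["mean"] = mu, _["sd"] = sd);
}

// Connected-component labelling of TRUE pixels (connectivity 4 or 8).
// Labels are 1-based in raster (row-major) discovery order; 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int dr4[] = {-1, 1, 0, 0};
  int dc4[] = {0, 0, -1, 1};
  int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  int ndir = (connectivity == 8) ? 8 : 4;
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < ndir; ++k) {
          int r2 = p.first + dr[k], c2 = p.second + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            q.push(std::make_pair(r2, c2));
          }
        }
      }
    }
  }
  return lab;
}

// 4-connected flood fill of TRUE pixels from a 0-based seed.
// [[Rcpp::export]]
LogicalMatrix cpp_flood4(LogicalMatrix mask, int seed_r, int seed_c) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), false);
  if (seed_r < 0 || seed_r >= nr || seed_c < 0 || seed_c >= nc)
    stop("seed out of bounds");
  if (!mask(seed_r, seed_c)) return out;
  int dr[] = {-1, 1, 0, 0};
  int dc[] = {0, 0, -1, 1};
  std::queue<std::pair<int, int> > q;
  out(seed_r, seed_c) = true;
  q.push(std::make_pair(seed_r, seed_c));
  while (!q.empty()) {
    std::pair<int, int> p = q.front();
    q.pop();
    for (int k = 0; k < 4; ++k) {
      int r2 = p.first + dr[k], c2 = p.second + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (mask(r2, c2) && !out(r2, c2)) {
        out(r2, c2) = true;
        q.push(std::make_pair(r2, c2));
      }
    }
  }
  return out;
}

// Guo-Hall two-subiteration thinning to a 1-pixel-wide, 8-connected
// skeleton. Pixels outside the image are treated as background. The
// skeleton is a subset of the input mask and preserves its topology.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix img(clone(mask));
  std::vector<std::pair<int, int> > kill;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int iter = 0; iter < 2; ++iter) {
      kill.clear();
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (!img(r, c)) continue;
          // neighbours p2..p9, clockwise from north
          bool p2 = (r > 0) && img(r - 1, c);
          bool p3 = (r > 0 && c < nc - 1) && img(r - 1, c + 1);
          bool p4 = (c < nc - 1) && img(r, c + 1);
          bool p5 = (r < nr - 1 && c < nc - 1) && img(r + 1, c + 1);
          bool p6 = (r < nr - 1) && img(r + 1, c);
          bool p7 = (r < nr - 1 && c > 0) && img(r + 1, c - 1);
          bool p8 = (c > 0) && img(r, c - 1);
          bool p9 = (r > 0 && c > 0) && img(r - 1, c - 1);
          int C = (int)((!p2) && (p3 || p4)) + (int)((!p4) && (p5 || p6)) +
                  (int)((!p6) && (p7 || p8)) + (int)((!p8) && (p9 || p2));
          int N1 = (int)(p9 || p2) + (int)(p3 || p4) + (int)(p5 || p6) +
                   (int)(p7 || p8);
          int N2 = (int)(p2 || p3) + (int)(p4 || p5) + (int)(p6 || p7) +
                   (int)(p8 || p9);
          int N = N1 < N2 ? N1 : N2;
          bool m = (iter == 0) ? ((p6 || p7 || !p9) && p8)
                               : ((p2 || p3 || !p5) && p4);
          if (C == 1 && N >= 2 && N <= 3 && !m) kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i)
        img(kill[i].first, kill[i].second) = false;
    }
  }
  return img;
}

// Rasterize anti-aliased thick segments (capsules) onto a canvas by
// maximum compositing. `segs` has columns x0, y0, x1, y1, w in pixel
// units (origin at the top-left corner, pixel centres at half-integers).
// [[Rcpp::export]]
NumericMatrix cpp_draw_segments(int nr, int nc, NumericMatrix segs) {
  NumericMatrix canvas(nr, nc);
  for (int s = 0; s < segs.nrow(); ++s) {
    double x0 = segs(s, 0), y0 = segs(s, 1);
    double x1 = segs(s, 2), y1 = segs(s, 3), w = segs(s, 4);
    double half = w / 2.0 + 0.5;
    int cmin = std::max(0, (int)std::floor(std::min(x0, x1) - half) - 1);
    int cmax = std::min(nc - 1, (int)std::ceil(std::max(x0, x1) + half));
    int rmin = std::max(0, (int)std::floor(std::min(y0, y1) - half) - 1);
    int rmax = std::min(nr - 1, (int)std::ceil(std::max(y0, y1) + half));
    double vx = x1 - x0, vy = y1 - y0;
    double len2 = vx * vx + vy * vy;
    for (int r = rmin; r <= rmax; ++r) {
      double py = r + 0.5;
      for (int c = cmin; c <= cmax; ++c) {
        double px = c + 0.5;
        double t = 0.0;
        if (len2 > 0) {
          t = ((px - x0) * vx + (py - y0) * vy) / len2;
          if (t < 0) t = 0;
          if (t > 1) t = 1;
        }
        double ddx = px - (x0 + t * vx), ddy = py - (y0 + t * vy);
        double d = std::sqrt(ddx * ddx + ddy * ddy);
        // crisp half-pixel edge ramp centred on the geometric boundary
        // (flow decorrelation saturates, so vessel edges are sharp);
        // coverage crosses 0.5 exactly at distance w/2
        double cov = (w / 2.0 + 0.25 - d) / 0.5;
        if (cov > 1) cov = 1;
        if (cov > canvas(r, c)) canvas(r, c) = cov;
      }
    }
  }
  return canvas;
}

// Moore-neighbour boundary tracing of the connected component containing
// the topmost-leftmost TRUE pixel, with Jacob's stopping criterion.
// Returns an n x 2 matrix of 0-based (row, col) contour pixels forming a
// closed 8-connected chain (the first pixel is not repeated at the end).
// [[Rcpp::export]]
IntegerMatrix cpp_trace_contour(LogicalMatrix region) {
  int nr = region.nrow(), nc = region.ncol();
  int sr = -1, sc = -1;
  for (int r = 0; r < nr && sr < 0; ++r)
    for (int c = 0; c < nc; ++c)
      if (region(r, c)) { sr = r; sc = c; break; }
  if (sr < 0) stop("empty region");
  // clockwise Moore neighbourhood starting east
  int dr[] = {0, 1, 1, 1, 0, -1, -1, -1};
  int dc[] = {1, 1, 0, -1, -1, -1, 0, 1};
  std::vector<int> rows, cols;
  // isolated pixel?
  bool isolated = true;
  for (int k = 0; k < 8; ++k) {
    int r2 = sr + dr[k], c2 = sc + dc[k];
    if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc && region(r2, c2))
      isolated = false;
  }
  if (isolated) {
    IntegerMatrix out(1, 2);
    out(0, 0) = sr;
    out(0, 1) = sc;
    return out;
  }
  // The raster-scan start pixel has no foreground neighbour among W, NW, N,
  // NE, so its west neighbour (possibly out of bounds) is background.
  int cr = sr, cc = sc;
  int br = sr, bc = sc - 1;  // backtrack: last background position examined
  int start_dir = -1;        // first exit direction from the start pixel
  int guard = 8 * nr * nc;
  while (guard-- > 0) {
    // direction from current pixel to the backtrack position
    int db = -1;
    for (int k = 0; k < 8; ++k)
      if (cr + dr[k] == br && cc + dc[k] == bc) { db = k; break; }
    // scan clockwise starting just after the backtrack position
    int found = -1;
    int lr = br, lc = bc;  // last background examined
    for (int k = 1; k <= 8; ++k) {
      int d = (db + k) % 8;
      int r2 = cr + dr[d], c2 = cc + dc[d];
      bool fg = (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc && region(r2, c2));
      if (fg) { found = d; break; }
      lr = r2; lc = c2;
    }
    if (found < 0) break;  // cannot happen for a non-isolated pixel
    if (cr == sr && cc == sc) {
      if (start_dir < 0) {
        start_dir = found;
      } else if (found == start_dir && !rows.empty()) {
        break;  // re-entered the start in the same direction: chain closed
      }
    }
    rows.push_back(cr);
    cols.push_back(cc);
    br = lr; bc = lc;
    cr += dr[found];
    cc += dc[found];
  }
  IntegerMatrix out((int)rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out((int)i, 0) = rows[i];
    out((int)i, 1) = cols[i];
  }
  return out;
}
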