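#include <Rcpp.h>
using namespace Rcpp;

// Median filter with square window of odd side k; borders replicate.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int k) {
  if (k < 1 || k % 2 == 0) stop("kernel must be odd and >= 1");
  int H = img.nrow(), W = img.ncol(), h = k / 2;
  if (k == 1) return clone(img);
  NumericMatrix out(H, W);
  std::vector<double> buf;
  buf.reserve((size_t)k * k);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      buf.clear();
      for (int dc = -h; dc <= h; ++dc) {
        int cc = std::min(std::max(c + dc, 0), W - 1);
        for (int dr = -h; dr <= h; ++dr) {
          int rr = std::min(std::max(r + dr, 0), H - 1);
          buf.push_back(img(rr, cc));
        }
      }
      std::nth_element(buf.begin(), buf.begin() + buf.size() / 2, buf.end());
      out(r, c) = buf[buf.size() / 2];
    }
  }
  return out;
}

// Two-segment least-squares changepoint cost per column.
//
// For each column c the rows [lo[c], hi[c]) (0-based, half open) are split
// at a candidate boundary r into an upper segment [lo, r) and a lower
// segment [r, hi); the cost stored at (r, c) is the summed squared
// residual of fitting each segment by its mean, divided by the number of
// rows. Minimising it over r estimates the step between two reflectivity
// levels using every pixel of the column, which is far more speckle-robust
// than a single-row gradient.
// [[Rcpp::export]]
NumericMatrix changepoint_cost_cpp(NumericMatrix img, IntegerVector lo,
                                   IntegerVector hi) {
  int H = img.nrow(), W = img.ncol();
  if (lo.size() != W || hi.size() != W) stop("band vectors must have one entry per column");
  NumericMatrix out(H, W);
  std::fill(out.begin(), out.end(), 1e30);
  std::vector<double> s1, s2;
  for (int c = 0; c < W; ++c) {
    int a = std::max((int)lo[c], 0), b = std::min((int)hi[c], H);
    int n = b - a;
    if (n <= 0) continue;
    s1.assign(n + 1, 0.0);
    s2.assign(n + 1, 0.0);
    for (int i = 0; i < n; ++i) {
      double v = img(a + i, c);
      s1[i + 1] = s1[i] + v;
      s2[i + 1] = s2[i] + v * v;
    }
    for (int r = a; r <= b && r < H; ++r) {
      int k = r - a, m = n - k;
      double sseA = (k > 0) ? s2[k] - s1[k] * s1[k] / k : 0.0;
      double sB1 = s1[n] - s1[k], sB2 = s2[n] - s2[k];
      double sseB = (m > 0) ? sB2 - sB1 * sB1 / m : 0.0;
      out(r, c) = (sseA + sseB) / n;
    }
  }
  return out;
}

// Minimum-cost left-to-right path on a precomputed cost image (same DP
// scheme and tie-breaking as dp_edge_path_cpp).
// [[Rcpp::export]]
IntegerVector dp_cost_path_cpp(NumericMatrix cost,
                               IntegerVector lo, IntegerVector hi,
                               int maxJump, double lambda) {
  int H = cost.nrow(), W = cost.ncol();
  if (lo.size() != W || hi.size() != W) stop("band vectors must have one entry per column");
  const double INF = 1e29, EPS = 1e-12;
  NumericMatrix D(H, W);
  IntegerMatrix from(H, W);
  for (int c = 0; c < W; ++c) {
    int a = std::max((int)lo[c], 0), b = std::min((int)hi[c], H - 1);
    if (a > b) stop("empty admissible band at column %d", c + 1);
    for (int r = 0; r < H; ++r) D(r, c) = INF;
    if (c == 0) {
      for (int r = a; r <= b; ++r) D(r, 0) = cost(r, 0);
    } else {
      int ap = std::max((int)lo[c - 1], 0), bp = std::min((int)hi[c - 1], H - 1);
      for (int r = a; r <= b; ++r) {
        double best = INF;
        int bestFrom = -1;
        for (int d = -maxJump; d <= maxJump; ++d) {
          int rp = r + d;
          if (rp < ap || rp > bp) continue;
          if (D(rp, c - 1) >= INF) continue;
          double v = D(rp, c - 1) + lambda * std::abs(d);
          if (v < best - EPS) { best = v; bestFrom = rp; }
        }
        if (bestFrom < 0) { D(r, c) = INF; from(r, c) = -1; }
        else { D(r, c) = best + cost(r, c); from(r, c) = bestFrom; }
      }
    }
  }
  int c = W - 1;
  int a = std::max((int)lo[c], 0), b = std::min((int)hi[c], H - 1);
  double best = INF;
  int r = -1;
  for (int rr = a; rr <= b; ++rr)
    if (D(rr, c) < best - EPS) { best = D(rr, c); r = rr; }
  if (r < 0 || best >= INF) stop("no admissible path");
  IntegerVector path(W);
  for (int cc = W - 1; cc >= 0; --cc) {
    path[cc] = r;
    if (cc > 0) r = from(r, cc);
  }
  return path;
}

// Minimum-cost left-to-right path on an edge-cost image.
//
// Cost of visiting row r in column c is -sign * (img(r,c) - img(r-1,c)),
// i.e. sign = +1 seeks dark-to-bright transitions (downward-increasing
// intensity), sign = -1 bright-to-dark. Rows are 0-based; admissible rows
// in column c are [max(lo[c],1), min(hi[c], H-1)]. Column-to-column jumps
// are limited to maxJump rows and penalised by lambda per row of jump.
// Ties resolve toward the smaller (more vitread) row.
// [[Rcpp::export]]
IntegerVector dp_edge_path_cpp(NumericMatrix img, double sign,
                               IntegerVector lo, IntegerVector hi,
                               int maxJump, double lambda) {
  int H = img.nrow(), W = img.ncol();
  if (lo.size() != W || hi.size() != W) stop("band vectors must have one entry per column");
  if (maxJump < 0) stop("maxJump must be >= 0");
  const double INF = 1e30, EPS = 1e-12;
  NumericMatrix D(H, W);
  IntegerMatrix from(H, W);
  for (int c = 0; c < W; ++c) {
    int a = std::max((int)lo[c], 1), b = std::min((int)hi[c], H - 1);
    if (a > b) stop("empty admissible band at column %d", c + 1);
    for (int r = 0; r < H; ++r) D(r, c) = INF;
    if (c == 0) {
      for (int r = a; r <= b; ++r)
        D(r, 0) = -sign * (img(r, 0) - img(r - 1, 0));
    } else {
      int ap = std::max((int)lo[c - 1], 1), bp = std::min((int)hi[c - 1], H - 1);
      for (int r = a; r <= b; ++r) {
        double best = INF;
        int bestFrom = -1;
        for (int d = -maxJump; d <= maxJump; ++d) {
          int rp = r + d;
          if (rp < ap || rp > bp) continue;
          if (D(rp, c - 1) >= INF) continue;
          double v = D(rp, c - 1) + lambda * std::abs(d);
          if (v < best - EPS) { best = v; bestFrom = rp; }
        }
        if (bestFrom < 0) {
          D(r, c) = INF;
          from(r, c) = -1;
        } else {
          D(r, c) = best - sign * (img(r, c) - img(r - 1, c));
          from(r, c) = bestFrom;
        }
      }
    }
  }
  int c = W - 1;
  int a = std::max((int)lo[c], 1), b = std::min((int)hi[c], H - 1);
  double best = INF;
  int r = -1;
  for (int rr = a; rr <= b; ++rr)
    if (D(rr, c) < best - EPS) { best = D(rr, c); r = rr; }
  if (r < 0 || best >= INF) stop("no admissible path");
  IntegerVector path(W);
  for (int cc = W - 1; cc >= 0; --cc) {
    path[cc] = r;
    if (cc > 0) r = from(r, cc);
  }
  return path;
}
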