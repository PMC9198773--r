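#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Scanpaths cross the C++ boundary as n x 3 matrices (x, y, duration),
// one row per fixation in temporal order. All geometry is done in screen
// pixels with the origin at the top-left corner and y increasing downward.

static inline double norm2(double a, double b) {
  return std::sqrt(a * a + b * b);
}

static inline double ang_diff(double a, double b) {
  // absolute angular difference wrapped to [0, pi]; inputs come from
  // atan2 so |a - b| <= 2*pi
  double d = std::fabs(a - b);
  while (d > 2.0 * M_PI) d -= 2.0 * M_PI;
  if (d > M_PI) d = 2.0 * M_PI - d;
  return d;
}

// Iterative scanpath simplification: successive saccade pairs are merged
// (the intervening fixation removed, vectors summed) when they either
// continue in a similar direction, or are both small with a brief fixation
// between them. Left-to-right greedy passes repeat until a fixpoint.
// [[Rcpp::export]]
NumericMatrix cpp_simplify(const NumericMatrix& fix, double direction_threshold,
                           double amplitude_threshold, double duration_threshold) {
  int n = fix.nrow();
  if (n < 2) stop("scanpath must have at least 2 fixations");
  std::vector<double> x(n), y(n), d(n);
  for (int i = 0; i < n; ++i) { x[i] = fix(i, 0); y[i] = fix(i, 1); d[i] = fix(i, 2); }

  bool changed = (n > 2);
  while (changed) {
    changed = false;
    size_t i = 0;
    while (i + 2 < x.size()) {
      double dx1 = x[i + 1] - x[i],     dy1 = y[i + 1] - y[i];
      double dx2 = x[i + 2] - x[i + 1], dy2 = y[i + 2] - y[i + 1];
      double a1 = norm2(dx1, dy1), a2 = norm2(dx2, dy2);
      bool dir_merge = ang_diff(std::atan2(dy2, dx2), std::atan2(dy1, dx1)) <
                       direction_threshold;
      bool amp_merge = (a1 < amplitude_threshold) && (a2 < amplitude_threshold) &&
                       (d[i + 1] < duration_threshold);
      if (dir_merge || amp_merge) {
        // merged vector = vector sum, i.e. drop the intervening fixation
        x.erase(x.begin() + i + 1);
        y.erase(y.begin() + i + 1);
        d.erase(d.begin() + i + 1);
        changed = true;   // stay at i: the merged vector may chain further
      } else {
        ++i;
      }
    }
  }

  int m = (int) x.size();
  NumericMatrix out(m, 3);
  for (int i = 0; i < m; ++i) { out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = d[i]; }
  return out;
}

// Shape-difference cost between every pair of saccadic vectors:
// entries[i][j] = Euclidean norm of (a_i - b_j).
// [[Rcpp::export]]
NumericMatrix cpp_cost_matrix(const NumericMatrix& fixA, const NumericMatrix& fixB) {
  int na = fixA.nrow() - 1, nb = fixB.nrow() - 1;
  if (na < 1 || nb < 1) stop("each scanpath must contribute at least one saccade");
  NumericMatrix C(na, nb);
  for (int i = 0; i < na; ++i) {
    double adx = fixA(i + 1, 0) - fixA(i, 0);
    double ady = fixA(i + 1, 1) - fixA(i, 1);
    for (int j = 0; j < nb; ++j) {
      double bdx = fixB(j + 1, 0) - fixB(j, 0);
      double bdy = fixB(j + 1, 1) - fixB(j, 1);
      C(i, j) = norm2(adx - bdx, ady - bdy);
    }
  }
  return C;
}

// Minimal-cost monotone path from (1,1) to (n,m) with steps
// {diagonal, right, down}; path cost = sum of entered cells, start
// included. Ties broken by preferring diagonal, then right, then down.
// Returns the path as a k x 2 matrix of 1-based (i, j) pairs.
// [[Rcpp::export]]
IntegerMatrix cpp_align(const NumericMatrix& cost) {
  int n = cost.nrow(), m = cost.ncol();
  if (n < 1 || m < 1) stop("cost matrix must be non-empty");
  NumericMatrix D(n, m);
  IntegerMatrix from(n, m);  // 0 start, 1 diagonal, 2 right (j-1), 3 down (i-1)
  D(0, 0) = cost(0, 0);
  from(0, 0) = 0;
  for (int j = 1; j < m; ++j) { D(0, j) = D(0, j - 1) + cost(0, j); from(0, j) = 2; }
  for (int i = 1; i < n; ++i) { D(i, 0) = D(i - 1, 0) + cost(i, 0); from(i, 0) = 3; }
  for (int i = 1; i < n; ++i) {
    for (int j = 1; j < m; ++j) {
      double diag = D(i - 1, j - 1), right = D(i, j - 1), down = D(i - 1, j);
      double best = diag; int f = 1;
      if (right < best) { best = right; f = 2; }
      if (down < best)  { best = down;  f = 3; }
      D(i, j) = best + cost(i, j);
      from(i, j) = f;
    }
  }
  // backtrace
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  while (true) {
    pi.push_back(i + 1); pj.push_back(j + 1);
    int f = from(i, j);
    if (f == 0) break;
    if (f == 1) { --i; --j; }
    else if (f == 2) { --j; }
    else { --i; }
  }
  int k = (int) pi.size();
  IntegerMatrix path(k, 2);
  for (int r = 0; r < k; ++r) { path(r, 0) = pi[k - 1 - r]; path(r, 1) = pj[k - 1 - r]; }
  return path;
}

// Five-dimension similarity over the aligned vector pairs.
// path holds 1-based saccade indices into A and B.
// [[Rcpp::export]]
NumericVector cpp_similarity(const NumericMatrix& fixA, const NumericMatrix& fixB,
                             const IntegerMatrix& path, double diagonal) {
  int k = path.nrow();
  if (k < 1) stop("alignment must contain at least one pair");
  double sp = 0.0, sd = 0.0, ssh = 0.0, sdi = 0.0, sl = 0.0;
  for (int r = 0; r < k; ++r) {
    int i = path(r, 0) - 1, j = path(r, 1) - 1;
    double adx = fixA(i + 1, 0) - fixA(i, 0), ady = fixA(i + 1, 1) - fixA(i, 1);
    double bdx = fixB(j + 1, 0) - fixB(j, 0), bdy = fixB(j + 1, 1) - fixB(j, 1);
    ssh += norm2(adx - bdx, ady - bdy) / (2.0 * diagonal);
    sdi += ang_diff(std::atan2(ady, adx), std::atan2(bdy, bdx)) / M_PI;
    sl  += std::fabs(norm2(adx, ady) - norm2(bdx, bdy)) / diagonal;
    sp  += norm2(fixA(i + 1, 0) - fixB(j + 1, 0),
                      fixA(i + 1, 1) - fixB(j + 1, 1)) / diagonal;
    double da = fixA(i + 1, 2), db = fixB(j + 1, 2);
    double mx = da > db ? da : db;
    sd += (mx > 0.0) ? std::fabs(da - db) / mx : 0.0;
  }
  NumericVector out = NumericVector::create(
    _["position"]  = 1.0 - sp  / k,
    _["duration"]  = 1.0 - sd  / k,
    _["shape"]     = 1.0 - ssh / k,
    _["direction"] = 1.0 - sdi / k,
    _["length"]    = 1.0 - sl  / k);
  // guard against off-screen fixations pushing a normalised difference past 1
  for (int q = 0; q < 5; ++q) { if (out[q] < 0.0) out[q] = 0.0; if (out[q] > 1.0) out[q] = 1.0; }
  return out;
}

// Full comparison of two fixation matrices: simplify -> cost -> align -> score.
// [[Rcpp::export]]
List cpp_compare(const NumericMatrix& fixA, const NumericMatrix& fixB,
                 double direction_threshold, double amplitude_threshold,
                 double duration_threshold, double diagonal, bool simplify = true) {
  NumericMatrix A = simplify ?
    cpp_simplify(fixA, direction_threshold, amplitude_threshold, duration_threshold) :
    fixA;
  NumericMatrix B = simplify ?
    cpp_simplify(fixB, direction_threshold, amplitude_threshold, duration_threshold) :
    fixB;
  NumericMatrix C = cpp_cost_matrix(A, B);
  IntegerMatrix path = cpp_align(C);
  NumericVector s = cpp_similarity(A, B, path, diagonal);
  return List::create(_["scores"] = s,
                      _["n_vectors"] = IntegerVector::create(A.nrow() - 1, B.nrow() - 1));
}

// Batch cross-comparison: every scanpath in encList against every scanpath
// in recList. Each list element is a fixation matrix; simplification is
// performed once per scanpath. Returns an nA x nB x 5 array of similarities.
// [[Rcpp::export]]
NumericVector cpp_cross_compare(List encList, List recList,
                                double direction_threshold, double amplitude_threshold,
                                double duration_threshold, double diagonal) {
  int na = encList.size(), nb = recList.size();
  std::vector<NumericMatrix> A(na), B(nb);
  for (int i = 0; i < na; ++i)
    A[i] = cpp_simplify(as<NumericMatrix>(encList[i]), direction_threshold,
                        amplitude_threshold, duration_threshold);
  for (int j = 0; j < nb; ++j)
    B[j] = cpp_simplify(as<NumericMatrix>(recList[j]), direction_threshold,
                        amplitude_threshold, duration_threshold);
  NumericVector out(Dimension(na, nb, 5));
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      NumericMatrix C = cpp_cost_matrix(A[i], B[j]);
      IntegerMatrix path = cpp_align(C);
      NumericVector s = cpp_similarity(A[i], B[j], path, diagonal);
      for (int q = 0; q < 5; ++q) out[i + na * j + na * nb * q] = s[q];
    }
  }
  return out;
}
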