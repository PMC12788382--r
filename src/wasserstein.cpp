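#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Minimum-cost perfect assignment on a square cost matrix (Hungarian
// algorithm with dual potentials, O(n^3)). Costs must be finite.
static double hungarian(const std::vector<double>& a, int n) {
  if (n == 0) return 0.0;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0), minv(n + 1);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  std::vector<char> used(n + 1);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::fill(minv.begin(), minv.end(), INF);
    std::fill(used.begin(), used.end(), 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = a[(i0 - 1) * n + (j - 1)] - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  double res = 0.0;
  for (int j = 1; j <= n; ++j) res += a[(p[j] - 1) * n + (j - 1)];
  return res;
}

// Ground distance between two diagram points under the internal norm
// (norm_type 0 = L-infinity, 1 = L2).
static inline double point_dist(double b1, double d1, double b2, double d2,
                                int norm_type) {
  double db = std::fabs(b1 - b2), dd = std::fabs(d1 - d2);
  if (norm_type == 0) return db > dd ? db : dd;
  return std::sqrt(db * db + dd * dd);
}

// Distance from a point to its orthogonal projection on the diagonal.
static inline double diag_dist(double b, double d, int norm_type) {
  double pers = std::fabs(d - b);
  if (norm_type == 0) return pers / 2.0;
  return pers / std::sqrt(2.0);
}

// q-Wasserstein between two finite diagrams given as (n x 2) matrices of
// (birth, death). Partial matching via an augmented (n+m) square assignment:
// each point of A may match a point of B or a "ghost" column standing for its
// diagonal projection (ghost blocks are row/column-constant, so ghosts are
// interchangeable and no infinite costs are needed).
static double wasserstein_pair(const double* A, int n, const double* B, int m,
                               double q, int norm_type) {
  if (n == 0 && m == 0) return 0.0;
  int N = n + m;
  bool unit_q = (q == 1.0);
  std::vector<double> cost((size_t)N * N, 0.0);
  for (int i = 0; i < n; ++i) {
    double bi = A[i], di = A[i + n];
    double dgi = diag_dist(bi, di, norm_type);
    if (!unit_q) dgi = std::pow(dgi, q);
    for (int j = 0; j < m; ++j) {
      double c = point_dist(bi, di, B[j], B[j + m], norm_type);
      cost[(size_t)i * N + j] = unit_q ? c : std::pow(c, q);
    }
    for (int j = m; j < N; ++j) cost[(size_t)i * N + j] = dgi;
  }
  for (int i = n; i < N; ++i)
    for (int j = 0; j < m; ++j) {
      double c = diag_dist(B[j], B[j + m], norm_type);
      cost[(size_t)i * N + j] = unit_q ? c : std::pow(c, q);
    }
  double total = hungarian(cost, N);
  if (total < 0) total = 0;  // guard tiny negative round-off
  return unit_q ? total : std::pow(total, 1.0 / q);
}

// [[Rcpp::export(name = ".wasserstein_cpp")]]
double wasserstein_cpp(NumericMatrix A, NumericMatrix B, double q,
                       int norm_type) {
  return wasserstein_pair(A.begin(), A.nrow(), B.begin(), B.nrow(),
                          q, norm_type);
}

// All-pairs q-Wasserstein over a list of finite diagrams (each an n_i x 2
// matrix). Only the upper triangle is solved; the result is mirrored.
// [[Rcpp::export(name = ".pairwise_wd_cpp")]]
NumericMatrix pairwise_wd_cpp(List diagrams, double q, int norm_type) {
  int T = diagrams.size();
  NumericMatrix D(T, T);
  std::vector<NumericMatrix> mats;
  mats.reserve(T);
  for (int t = 0; t < T; ++t) mats.push_back(as<NumericMatrix>(diagrams[t]));
  for (int i = 0; i < T; ++i) {
    for (int j = i + 1; j < T; ++j) {
      double w = wasserstein_pair(mats[i].begin(), mats[i].nrow(),
                                  mats[j].begin(), mats[j].nrow(),
                                  q, norm_type);
      D(i, j) = w;
      D(j, i) = w;
    }
    Rcpp::checkUserInterrupt();
  }
  return D;
}
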