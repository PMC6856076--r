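#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Solve the p x p normal system assembled from rows/cols `idx` of the full
// Gram matrix, by Cholesky with a ridge fallback on pivot failure.
// Returns rss; writes coefficients into `beta`. Sets `deficient` on fallback.
static double solve_subset(const double *gram, const double *xty, int G,
                           const int *idx, int p, double yty,
                           std::vector<double> &A, std::vector<double> &b,
                           std::vector<double> &beta, bool &deficient) {
  for (int i = 0; i < p; ++i) {
    b[i] = xty[idx[i]];
    for (int j = 0; j <= i; ++j) {
      A[i * p + j] = gram[idx[i] * (R_xlen_t)G + idx[j]];
    }
  }
  // scale for pivot tolerance
  double dmax = 0.0;
  for (int i = 0; i < p; ++i) dmax = std::max(dmax, A[i * p + i]);
  const double tol = 1e-12 * std::max(dmax, 1.0);

  // Cholesky A = L L' (lower triangle in place)
  deficient = false;
  std::vector<double> L(A);
  bool ok = true;
  for (int j = 0; j < p; ++j) {
    double d = L[j * p + j];
    for (int k = 0; k < j; ++k) d -= L[j * p + k] * L[j * p + k];
    if (d <= tol) { ok = false; break; }
    d = std::sqrt(d);
    L[j * p + j] = d;
    for (int i = j + 1; i < p; ++i) {
      double s = L[i * p + j];
      for (int k = 0; k < j; ++k) s -= L[i * p + k] * L[j * p + k];
      L[i * p + j] = s / d;
    }
  }
  if (!ok) {
    // tiny ridge keeps the search going on a collinear subset
    deficient = true;
    L = A;
    double ridge = 1e-8 * std::max(dmax, 1.0);
    for (int j = 0; j < p; ++j) {
      double d = L[j * p + j] + ridge;
      for (int k = 0; k < j; ++k) d -= L[j * p + k] * L[j * p + k];
      if (d <= 0) d = ridge;
      d = std::sqrt(d);
      L[j * p + j] = d;
      for (int i = j + 1; i < p; ++i) {
        double s = L[i * p + j];
        for (int k = 0; k < j; ++k) s -= L[i * p + k] * L[j * p + k];
        L[i * p + j] = s / d;
      }
    }
  }
  // forward/back substitution
  for (int i = 0; i < p; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i * p + k] * beta[k];
    beta[i] = s / L[i * p + i];
  }
  for (int i = p - 1; i >= 0; --i) {
    double s = beta[i];
    for (int k = i + 1; k < p; ++k) s -= L[k * p + i] * beta[k];
    beta[i] = s / L[i * p + i];
  }
  // rss = y'y - 2 b'X'y + b'A b (exact for the ridge fallback too)
  double quad = 0.0, lin = 0.0;
  for (int i = 0; i < p; ++i) {
    lin += beta[i] * b[i];
    double s = 0.0;
    for (int j = 0; j < p; ++j) {
      double a = (j <= i) ? A[i * p + j] : A[j * p + i];
      s += a * beta[j];
    }
    quad += beta[i] * s;
  }
  double rss = yty - 2.0 * lin + quad;
  return rss > 0 ? rss : 0.0;
}

// Exhaustive best-subset search over all size-k combinations of `candidates`
// (0-based column indices into the Gram matrix). `fixed` holds design columns
// present in every model (intercept and the target's own lag). Combinations
// are enumerated in lexicographic order of the candidate vector, and ties in
// rss (within 1e-12 relative) keep the earliest combination, so the result is
// deterministic under the caller's canonical gene order.
// [[Rcpp::export]]
List best_subset_search(NumericMatrix gram, NumericVector xty, double yty,
                        IntegerVector fixed, IntegerVector candidates,
                        int k) {
  const int G = gram.nrow();
  const int nf = fixed.size();
  const int nc = candidates.size();
  const int p = nf + k;
  if (k <= 0) stop("k must be positive");
  if (nc < k) stop("fewer candidates than k");

  std::vector<int> idx(p);
  for (int i = 0; i < nf; ++i) idx[i] = fixed[i];
  std::vector<int> comb(k);
  for (int i = 0; i < k; ++i) comb[i] = i;

  std::vector<double> A(p * p), b(p), beta(p);
  std::vector<double> best_beta(p);
  std::vector<int> best_comb(k, -1);
  double best_rss = R_PosInf;
  bool best_def = false;

  const double *gp = REAL(gram);
  const double *xp = REAL(xty);

  while (true) {
    for (int i = 0; i < k; ++i) idx[nf + i] = candidates[comb[i]];
    bool def;
    double rss = solve_subset(gp, xp, G, idx.data(), p, yty, A, b, beta, def);
    if (best_comb[0] < 0 ||
        rss < best_rss - 1e-12 * std::max(1.0, best_rss)) {
      best_rss = rss;
      best_def = def;
      for (int i = 0; i < k; ++i) best_comb[i] = comb[i];
      best_beta = beta;
    }
    // next lexicographic combination
    int i = k - 1;
    while (i >= 0 && comb[i] == nc - k + i) --i;
    if (i < 0) break;
    ++comb[i];
    for (int j = i + 1; j < k; ++j) comb[j] = comb[j - 1] + 1;
  }

  IntegerVector chosen(k);
  for (int i = 0; i < k; ++i) chosen[i] = candidates[best_comb[i]];
  NumericVector coef(p);
  for (int i = 0; i < p; ++i) coef[i] = best_beta[i];
  return List::create(_["subset"] = chosen, _["coefficients"] = coef,
                      _["rss"] = best_rss, _["rank_deficient"] = best_def);
}
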