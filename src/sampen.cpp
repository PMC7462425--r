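#include <Rcpp.h>
#include <map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Template-match pair counts for sample entropy.
//
// Standard (self-match excluded) convention: among the N - m templates of
// length m taken at positions 1..N-m, B counts ordered pairs (i, j), i != j,
// whose Chebyshev distance over the first m components is <= r; A counts the
// same pairs over all m + 1 components.  SampEn = -log(A / B); the shared
// normalisation cancels.
//
// Walk-strength series take values on a small alphabet (one value per node),
// so identical embedding vectors repeat heavily.  When profitable, counting
// is done over distinct (m+1)-grams weighted by their frequencies; this is
// algebraically identical to the direct pair loop (same doubles, same
// closed-tolerance comparison), only grouped.

static inline bool cheb_match(const double *x, int i, int j, int len, double r) {
  for (int k = 0; k < len; ++k) {
    double d = x[i + k] - x[j + k];
    if (d < 0) d = -d;
    if (d > r) return false;
  }
  return true;
}

// [[Rcpp::export]]
List sampen_counts_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  const int nt = N - m;  // number of (m+1)-length templates / restricted m-templates
  if (nt < 2) stop("series too short for embedding dimension m");
  const double *xp = REAL(x);

  // distinct-value coding
  std::vector<double> u(xp, xp + N);
  std::sort(u.begin(), u.end());
  u.erase(std::unique(u.begin(), u.end()), u.end());
  const int U = (int)u.size();

  double B = 0.0, A = 0.0;
  bool dedup = (U <= 2048);
  if (dedup) {
    std::vector<int> code(N);
    for (int i = 0; i < N; ++i)
      code[i] = (int)(std::lower_bound(u.begin(), u.end(), xp[i]) - u.begin());

    // group identical (m+1)-grams
    std::map<std::vector<int>, int> grams;
    std::vector<int> key(m + 1);
    for (int i = 0; i < nt; ++i) {
      for (int k = 0; k <= m; ++k) key[k] = code[i + k];
      ++grams[key];
    }
    const int G = (int)grams.size();
    if ((double)G * G <= 0.5 * (double)nt * nt + 1e6) {
      std::vector<char> match((size_t)U * U);
      for (int a = 0; a < U; ++a)
        for (int b = 0; b < U; ++b)
          match[(size_t)a * U + b] = (std::abs(u[a] - u[b]) <= r) ? 1 : 0;

      std::vector<std::vector<int>> gv; gv.reserve(G);
      std::vector<double> gf; gf.reserve(G);
      for (auto &kv : grams) { gv.push_back(kv.first); gf.push_back((double)kv.second); }

      // grams are in lexicographic order, so grams whose first component
      // lies within tolerance of a given code form one contiguous run:
      // iterate only that band and check the remaining components
      std::vector<int> lo(U), hi(U);
      { int l = 0;
        for (int a = 0; a < U; ++a) { while (u[a] - u[l] > r) ++l; lo[a] = l; } }
      { int h = U - 1;
        for (int a = U - 1; a >= 0; --a) { while (u[h] - u[a] > r) --h; hi[a] = h; } }
      std::vector<int> gstart(U + 1);
      { int gi = 0;
        for (int c = 0; c <= U; ++c) {
          while (gi < G && gv[gi][0] < c) ++gi;
          gstart[c] = gi;
        } }

      double SB = 0.0, SA = 0.0;  // ordered pairs including i == j
      for (int g = 0; g < G; ++g) {
        const std::vector<int> &a = gv[g];
        const int h1 = gstart[hi[a[0]] + 1];
        for (int h = gstart[lo[a[0]]]; h < h1; ++h) {
          const std::vector<int> &b = gv[h];
          bool okm = true;
          for (int k = 1; k < m; ++k)
            if (!match[(size_t)a[k] * U + b[k]]) { okm = false; break; }
          if (!okm) continue;
          const double w = gf[g] * gf[h];
          SB += w;
          if (match[(size_t)a[m] * U + b[m]]) SA += w;
        }
      }
      B = SB - nt;  // remove self-matches
      A = SA - nt;
      return List::create(_["A"] = A, _["B"] = B, _["n_templates"] = nt);
    }
    // fall through to direct loop if too many distinct grams
  }

  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      if (!cheb_match(xp, i, j, m, r)) continue;
      B += 2.0;
      double d = xp[i + m] - xp[j + m];
      if (d < 0) d = -d;
      if (d <= r) A += 2.0;
    }
  }
  return List::create(_["A"] = A, _["B"] = B, _["n_templates"] = nt);
}

// Literal printed-formula variant: self-matches included, per-level index
// ranges as printed (m-templates j = 1..N-m+1 with 1/(N-m+1) normalisation,
// (m+1)-templates j = 1..N-m with 1/(N-m); outer i = 1..N-m in both).
// Returns normalised B and A.
// [[Rcpp::export]]
List sampen_counts_printed_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  const int nB = N - m + 1, nA = N - m;
  if (nA < 1) stop("series too short for embedding dimension m");
  const double *xp = REAL(x);
  double Bsum = 0.0, Asum = 0.0;
  for (int i = 0; i < nA; ++i) {
    for (int j = 0; j < nB; ++j)
      if (cheb_match(xp, i, j, m, r)) Bsum += 1.0;
    for (int j = 0; j < nA; ++j)
      if (cheb_match(xp, i, j, m + 1, r)) Asum += 1.0;
  }
  double B = Bsum / ((double)nA * (double)nB);
  double A = Asum / ((double)nA * (double)nA);
  return List::create(_["A"] = A, _["B"] = B, _["n_templates"] = nA);
}
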