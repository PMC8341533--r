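#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// One simplex prediction: k nearest library rows to the query row under
// Euclidean distance, exponential weights exp(-d / d_min) normalized to sum
// one; if d_min == 0 the zero-distance neighbors share uniform weight.
// Library rows temporally within `excl` samples of the query are ineligible.
//
// Returns false (insufficient library) or fills `widx` / `w` with the chosen
// neighbor rows (0-based) and their weights.
static bool simplex_neighbors(const NumericMatrix &states,
                              const IntegerVector &row_times,
                              const std::vector<int> &lib, int query,
                              int knn, int excl,
                              std::vector<int> &widx, std::vector<double> &w) {
  const int ncol = states.ncol();
  const int qt = row_times[query];
  std::vector<std::pair<double, int> > cand;
  cand.reserve(lib.size());
  for (size_t j = 0; j < lib.size(); ++j) {
    const int l = lib[j];
    if (std::abs(row_times[l] - qt) <= excl) continue;
    double d2 = 0.0;
    for (int c = 0; c < ncol; ++c) {
      const double diff = states(query, c) - states(l, c);
      d2 += diff * diff;
    }
    cand.push_back(std::make_pair(d2, l));
  }
  if ((int)cand.size() < knn) return false;
  std::partial_sort(cand.begin(), cand.begin() + knn, cand.end());
  const double dmin = std::sqrt(cand[0].first);
  widx.resize(knn);
  w.resize(knn);
  if (dmin == 0.0) {
    int nzero = 0;
    for (int k = 0; k < knn; ++k)
      if (cand[k].first == 0.0) ++nzero;
    for (int k = 0; k < knn; ++k) {
      widx[k] = cand[k].second;
      w[k] = (cand[k].first == 0.0) ? 1.0 / nzero : 0.0;
    }
  } else {
    double wsum = 0.0;
    for (int k = 0; k < knn; ++k) {
      widx[k] = cand[k].second;
      w[k] = std::exp(-std::sqrt(cand[k].first) / dmin);
      wsum += w[k];
    }
    for (int k = 0; k < knn; ++k) w[k] /= wsum;
  }
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_simplex_predict(NumericMatrix states, IntegerVector row_times,
                                  NumericVector target_by_row,
                                  IntegerVector lib, IntegerVector query,
                                  int knn, int excl) {
  std::vector<int> lib0(lib.size());
  for (int i = 0; i < lib.size(); ++i) lib0[i] = lib[i] - 1;
  NumericVector pred(query.size(), NA_REAL);
  std::vector<int> widx;
  std::vector<double> w;
  for (int i = 0; i < query.size(); ++i) {
    const int q = query[i] - 1;
    if (!simplex_neighbors(states, row_times, lib0, q, knn, excl, widx, w))
      continue;
    double p = 0.0;
    for (size_t k = 0; k < widx.size(); ++k)
      p += w[k] * target_by_row[widx[k]];
    pred[i] = p;
  }
  return pred;
}

// Dense neighbor-weight matrix: rows = queries, columns = embedding rows.
// pred = W %*% target_by_row; the matrix is target-independent, so one
// matrix serves every phase-randomized surrogate of the target series.
// Queries with an insufficient library get an all-NA row.
// [[Rcpp::export]]
NumericMatrix cpp_simplex_weights(NumericMatrix states, IntegerVector row_times,
                                  IntegerVector lib, IntegerVector query,
                                  int knn, int excl) {
  std::vector<int> lib0(lib.size());
  for (int i = 0; i < lib.size(); ++i) lib0[i] = lib[i] - 1;
  NumericMatrix W(query.size(), states.nrow());
  std::vector<int> widx;
  std::vector<double> w;
  for (int i = 0; i < query.size(); ++i) {
    const int q = query[i] - 1;
    if (!simplex_neighbors(states, row_times, lib0, q, knn, excl, widx, w)) {
      for (int c = 0; c < W.ncol(); ++c) W(i, c) = NA_REAL;
      continue;
    }
    for (size_t k = 0; k < widx.size(); ++k) W(i, widx[k]) = w[k];
  }
  return W;
}
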