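#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Data are processed transposed (points as contiguous columns of a d x n
// buffer) so the inner distance loops stream through memory.

static void transpose_into(const NumericMatrix &X, std::vector<double> &buf) {
  const int n = X.nrow(), p = X.ncol();
  buf.resize(static_cast<size_t>(n) * p);
  for (int j = 0; j < p; ++j) {
    const double *col = &X(0, j);
    for (int i = 0; i < n; ++i) buf[static_cast<size_t>(i) * p + j] = col[i];
  }
}

static inline double l1(const double *a, const double *b, int p) {
  double d = 0.0;
  for (int j = 0; j < p; ++j) d += std::fabs(a[j] - b[j]);
  return d;
}

// Nearest-centroid L1 distances: for each row of X, the distance to its
// closest row of C and that row's index (1-based).
// [[Rcpp::export(name = ".l1_nearest")]]
List l1_nearest(NumericMatrix X, NumericMatrix C) {
  const int n = X.nrow(), k = C.nrow(), p = X.ncol();
  std::vector<double> xt, ct;
  transpose_into(X, xt);
  transpose_into(C, ct);
  IntegerVector lab(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    const double *xi = &xt[static_cast<size_t>(i) * p];
    double best = R_PosInf;
    int bi = 0;
    for (int c = 0; c < k; ++c) {
      double d = l1(xi, &ct[static_cast<size_t>(c) * p], p);
      if (d < best) { best = d; bi = c; }
    }
    lab[i] = bi + 1;
    dist[i] = best;
  }
  return List::create(_["labels"] = lab, _["dist"] = dist);
}

static void update_medians(const std::vector<double> &xt, int n, int p,
                           const std::vector<int> &lab, int k,
                           std::vector<double> &ct) {
  std::vector< std::vector<int> > members(k);
  for (int i = 0; i < n; ++i) members[lab[i]].push_back(i);
  std::vector<double> buf;
  for (int c = 0; c < k; ++c) {
    const std::vector<int> &m = members[c];
    if (m.empty()) continue;  // handled by caller
    buf.resize(m.size());
    double *cc = &ct[static_cast<size_t>(c) * p];
    for (int j = 0; j < p; ++j) {
      for (size_t t = 0; t < m.size(); ++t)
        buf[t] = xt[static_cast<size_t>(m[t]) * p + j];
      const size_t mid = m.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double med = buf[mid];
      if (m.size() % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + mid);
        med = 0.5 * (med + lo);
      }
      cc[j] = med;
    }
  }
}

// Lloyd iterations for k-medians under the Manhattan distance: assign each
// point to the nearest centroid, update centroids as element-wise medians,
// reseed empty clusters to the farthest point. Returns labels, centroids,
// total objective, and the per-iteration objective trace.
// [[Rcpp::export(name = ".kmedians_lloyd")]]
List kmedians_lloyd(NumericMatrix X, NumericMatrix C_init, int max_iter) {
  const int n = X.nrow(), p = X.ncol(), k = C_init.nrow();
  std::vector<double> xt, ct;
  transpose_into(X, xt);
  transpose_into(C_init, ct);
  std::vector<int> lab(n, 0), prev(n, -1);
  std::vector<double> dist(n, 0.0);
  std::vector<double> trace;
  int iter = 0;
  bool converged = false;
  for (iter = 0; iter < max_iter; ++iter) {
    for (int i = 0; i < n; ++i) {
      const double *xi = &xt[static_cast<size_t>(i) * p];
      double best = R_PosInf;
      int bi = 0;
      for (int c = 0; c < k; ++c) {
        double d = l1(xi, &ct[static_cast<size_t>(c) * p], p);
        if (d < best) { best = d; bi = c; }
      }
      lab[i] = bi;
      dist[i] = best;
    }
    // empty-cluster repair: move the centroid onto the farthest point
    std::vector<int> count(k, 0);
    for (int i = 0; i < n; ++i) count[lab[i]]++;
    for (int c = 0; c < k; ++c) {
      if (count[c] == 0) {
        int far = 0;
        double fd = -1.0;
        for (int i = 0; i < n; ++i)
          if (dist[i] > fd && count[lab[i]] > 1) { fd = dist[i]; far = i; }
        count[lab[far]]--;
        lab[far] = c;
        count[c] = 1;
        dist[far] = 0.0;
      }
    }
    double obj = 0.0;
    for (int i = 0; i < n; ++i) obj += dist[i];
    trace.push_back(obj);
    if (lab == prev) { converged = true; break; }
    prev = lab;
    update_medians(xt, n, p, lab, k, ct);
  }
  // final consistency: labels and objective against the final centroids
  IntegerVector lab_out(n);
  NumericMatrix C_out(k, p);
  double obj = 0.0;
  for (int i = 0; i < n; ++i) {
    const double *xi = &xt[static_cast<size_t>(i) * p];
    double best = R_PosInf;
    int bi = 0;
    for (int c = 0; c < k; ++c) {
      double d = l1(xi, &ct[static_cast<size_t>(c) * p], p);
      if (d < best) { best = d; bi = c; }
    }
    lab_out[i] = bi + 1;
    obj += best;
  }
  for (int c = 0; c < k; ++c)
    for (int j = 0; j < p; ++j) C_out(c, j) = ct[static_cast<size_t>(c) * p + j];
  return List::create(_["labels"] = lab_out, _["centroids"] = C_out,
                      _["objective"] = obj,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["iterations"] = iter + 1,
                      _["converged"] = converged);
}

// k-means++-style seeding under L1: first centroid uniform (index passed
// in), then sample proportional to the distance to the nearest chosen
// centroid. `u` supplies the k-1 uniform variates from R's RNG.
// [[Rcpp::export(name = ".kmeanspp_l1_idx")]]
IntegerVector kmeanspp_l1_idx(NumericMatrix X, int k, int first,
                              NumericVector u) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> xt;
  transpose_into(X, xt);
  IntegerVector idx(k);
  idx[0] = first;
  std::vector<double> d(n);
  const double *c0 = &xt[static_cast<size_t>(first - 1) * p];
  for (int i = 0; i < n; ++i) d[i] = l1(&xt[static_cast<size_t>(i) * p], c0, p);
  for (int j = 1; j < k; ++j) {
    double tot = 0.0;
    for (int i = 0; i < n; ++i) tot += d[i];
    int pick = 0;
    if (tot <= 0) {
      pick = static_cast<int>(u[j - 1] * n);
      if (pick >= n) pick = n - 1;
    } else {
      double target = u[j - 1] * tot, acc = 0.0;
      for (int i = 0; i < n; ++i) {
        acc += d[i];
        if (acc >= target) { pick = i; break; }
      }
    }
    idx[j] = pick + 1;
    const double *cj = &xt[static_cast<size_t>(pick) * p];
    for (int i = 0; i < n; ++i) {
      double di = l1(&xt[static_cast<size_t>(i) * p], cj, p);
      if (di < d[i]) d[i] = di;
    }
  }
  idx;
  return idx;
}
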