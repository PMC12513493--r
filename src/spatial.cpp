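#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// k nearest neighbours by exhaustive scan; ties in distance broken by lower
// index so results are deterministic. Returns 1-based indices, n x k.
// [[Rcpp::export]]
IntegerMatrix knn_brute_cpp(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  IntegerMatrix out(n, k);
  std::vector<double> d(n);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      const double dx = x[i] - x[j], dy = y[i] - y[j];
      d[j] = dx * dx + dy * dy;
    }
    d[i] = R_PosInf;  // self excluded
    std::iota(idx.begin(), idx.end(), 0);
    std::partial_sort(idx.begin(), idx.begin() + k, idx.end(),
                      [&](int a, int b) {
                        return d[a] < d[b] || (d[a] == d[b] && a < b);
                      });
    for (int m = 0; m < k; ++m) out(i, m) = idx[m] + 1;
  }
  return out;
}

// For each point in A, Euclidean distance to the nearest point in B.
// a_id/b_id are identifiers used to exclude self-matches when A and B
// overlap (pass distinct ids otherwise).
// [[Rcpp::export]]
NumericVector nn_min_dist_cpp(NumericVector ax, NumericVector ay,
                              NumericVector bx, NumericVector by,
                              IntegerVector a_id, IntegerVector b_id) {
  const int na = ax.size(), nb = bx.size();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      if (b_id[j] == a_id[i]) continue;
      const double dx = ax[i] - bx[j], dy = ay[i] - by[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

static void score_matrix(const IntegerMatrix& nbr, const std::vector<int>& lab,
                         const LogicalVector& focal, int L,
                         std::vector<double>& score, std::vector<int>& nA) {
  const int n = nbr.nrow(), k = nbr.ncol();
  std::fill(score.begin(), score.end(), 0.0);
  std::fill(nA.begin(), nA.end(), 0);
  for (int i = 0; i < n; ++i) {
    if (!focal[i]) continue;
    const int a = lab[i];
    ++nA[a];
    for (int m = 0; m < k; ++m) score[a * L + lab[nbr(i, m) - 1]] += 1.0;
  }
  for (int a = 0; a < L; ++a) {
    if (nA[a] == 0) {
      for (int b = 0; b < L; ++b) score[a * L + b] = NA_REAL;
    } else {
      for (int b = 0; b < L; ++b) score[a * L + b] /= nA[a];
    }
  }
}

// Neighbourhood interaction scores with a label-permutation null.
// nbr: n x k matrix of 1-based neighbour indices (fixed across permutations).
// labels: 0-based phenotype codes. focal: which cells are scored as the
// focal (A) cell; labels are shuffled over all cells while positions and
// the focal mask stay put. Uses R's RNG (seed with set.seed upstream).
// [[Rcpp::export]]
List perm_interaction_cpp(IntegerMatrix nbr, IntegerVector labels,
                          LogicalVector focal, int L, int n_perm) {
  const int n = nbr.nrow();
  std::vector<int> lab(n);
  for (int i = 0; i < n; ++i) lab[i] = labels[i];

  std::vector<double> obs(L * L), sc(L * L);
  std::vector<int> nA(L), nAp(L);
  score_matrix(nbr, lab, focal, L, obs, nA);

  std::vector<double> psum(L * L, 0.0), psumsq(L * L, 0.0);
  std::vector<int> ge(L * L, 0), le(L * L, 0), nvalid(L * L, 0);
  const double eps = 1e-9;

  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates shuffle of the label vector
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(lab[i], lab[j]);
    }
    score_matrix(nbr, lab, focal, L, sc, nAp);
    for (int c = 0; c < L * L; ++c) {
      const double s = sc[c], o = obs[c];
      if (ISNAN(s) || ISNAN(o)) continue;
      ++nvalid[c];
      psum[c] += s;
      psumsq[c] += s * s;
      if (s >= o - eps) ++ge[c];
      if (s <= o + eps) ++le[c];
    }
  }

  NumericMatrix obs_m(L, L), mean_m(L, L), sd_m(L, L);
  IntegerMatrix ge_m(L, L), le_m(L, L), nv_m(L, L);
  IntegerVector nA_v(L);
  for (int a = 0; a < L; ++a) {
    nA_v[a] = nA[a];
    for (int b = 0; b < L; ++b) {
      const int c = a * L + b;
      obs_m(a, b) = obs[c];
      if (nvalid[c] > 0) {
        const double m = psum[c] / nvalid[c];
        mean_m(a, b) = m;
        const double v = psumsq[c] / nvalid[c] - m * m;
        sd_m(a, b) = std::sqrt(std::max(0.0, v));
      } else {
        mean_m(a, b) = NA_REAL;
        sd_m(a, b) = NA_REAL;
      }
      ge_m(a, b) = ge[c];
      le_m(a, b) = le[c];
      nv_m(a, b) = nvalid[c];
    }
  }
  return List::create(_["observed"] = obs_m, _["perm_mean"] = mean_m,
                      _["perm_sd"] = sd_m, _["n_ge"] = ge_m, _["n_le"] = le_m,
                      _["n_valid"] = nv_m, _["n_focal"] = nA_v);
}

// Exact 1-D k-means by dynamic programming on sorted values (SSE-optimal
// partition into K contiguous segments). Used to initialise the mixture
// fit: deterministic and immune to the local optima of Lloyd's algorithm.
// Returns 1-based segment membership for each element of x_sorted.
// [[Rcpp::export]]
IntegerVector ckmeans_dp_cpp(NumericVector x_sorted, int K) {
  const int n = x_sorted.size();
  std::vector<double> s1(n + 1, 0.0), s2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    s1[i + 1] = s1[i] + x_sorted[i];
    s2[i + 1] = s2[i] + x_sorted[i] * x_sorted[i];
  }
  auto cost = [&](int j, int i) {  // SSE of x[j..i], 0-based inclusive
    const double len = i - j + 1;
    const double sum = s1[i + 1] - s1[j];
    return (s2[i + 1] - s2[j]) - sum * sum / len;
  };
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<std::vector<double>> D(K + 1, std::vector<double>(n + 1, INF));
  std::vector<std::vector<int>> B(K + 1, std::vector<int>(n + 1, 0));
  D[0][0] = 0.0;
  for (int k = 1; k <= K; ++k) {
    for (int i = k; i <= n; ++i) {
      for (int j = k; j <= i; ++j) {  // segment covers x[j-1 .. i-1]
        const double c = D[k - 1][j - 1] + cost(j - 1, i - 1);
        if (c < D[k][i]) { D[k][i] = c; B[k][i] = j; }
      }
    }
  }
  IntegerVector out(n);
  int i = n;
  for (int k = K; k >= 1; --k) {
    const int j = B[k][i];
    for (int t = j; t <= i; ++t) out[t - 1] = k;
    i = j - 1;
  }
  return out;
}
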