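// Brute-force neighborhood search and per-point tensor accumulation.
// N is a few thousand points for typical single-plant clouds, so the
// O(N^2) distance pass is cheap and avoids a spatial-index dependency.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// k nearest neighbors (excluding self), 1-based indices, row i = point i.
// [[Rcpp::export]]
IntegerMatrix cpp_knn(const arma::mat& pts, const int k) {
  const int n = pts.n_rows;
  if (k < 1 || k > n - 1) stop("k must be in [1, n-1]");
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int> > d(n);
  for (int i = 0; i < n; ++i) {
    const arma::rowvec pi = pts.row(i);
    for (int j = 0; j < n; ++j) {
      const arma::rowvec diff = pts.row(j) - pi;
      d[j] = std::make_pair(arma::dot(diff, diff), j);
    }
    d[i].first = arma::datum::inf;  // exclude self
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int m = 0; m < k; ++m) out(i, m) = d[m].second + 1;
    // restore for next iteration (d rebuilt anyway)
  }
  return out;
}

// All neighbors within radius r (excluding self); list of 1-based vectors.
// [[Rcpp::export]]
List cpp_radius_neighbors(const arma::mat& pts, const double r) {
  const int n = pts.n_rows;
  const double r2 = r * r;
  List out(n);
  std::vector<int> buf;
  for (int i = 0; i < n; ++i) {
    buf.clear();
    const arma::rowvec pi = pts.row(i);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const arma::rowvec diff = pts.row(j) - pi;
      if (arma::dot(diff, diff) <= r2) buf.push_back(j + 1);
    }
    out[i] = IntegerVector(buf.begin(), buf.end());
  }
  return out;
}

// First/second-order tensors and eigen-structure for every point.
// nbrs: list of 1-based neighbor index vectors. Degenerate points
// (fewer than minNeighbors) get NA rows.
// [[Rcpp::export]]
List cpp_tensor_field(const arma::mat& pts, const List& nbrs,
                      const int minNeighbors) {
  const int n = pts.n_rows;
  arma::mat t1(n, 3, arma::fill::value(arma::datum::nan));
  arma::mat t2(n, 6, arma::fill::value(arma::datum::nan));   // xx xy xz yy yz zz
  arma::mat eval(n, 3, arma::fill::value(arma::datum::nan)); // descending
  arma::mat evec(n, 9, arma::fill::value(arma::datum::nan)); // v1 v2 v3 stacked
  arma::vec meanDist(n, arma::fill::value(arma::datum::nan));
  arma::ivec cnt(n, arma::fill::zeros);
  LogicalVector degen(n);

  for (int i = 0; i < n; ++i) {
    IntegerVector nb = nbrs[i];
    const int m = nb.size();
    cnt[i] = m;
    if (m < minNeighbors) { degen[i] = true; continue; }
    degen[i] = false;
    const arma::rowvec xi = pts.row(i);
    arma::rowvec tsum(3, arma::fill::zeros);
    arma::mat T(3, 3, arma::fill::zeros);
    double dsum = 0.0;
    for (int q = 0; q < m; ++q) {
      const arma::rowvec dj = pts.row(nb[q] - 1) - xi;  // x_j - x_i
      tsum -= dj;                                       // t_i = sum(x_i - x_j)
      T += dj.t() * dj;
      dsum += arma::norm(dj, 2);
    }
    t1.row(i) = tsum;
    t2(i, 0) = T(0, 0); t2(i, 1) = T(0, 1); t2(i, 2) = T(0, 2);
    t2(i, 3) = T(1, 1); t2(i, 4) = T(1, 2); t2(i, 5) = T(2, 2);
    meanDist[i] = dsum / m;

    arma::vec ev; arma::mat V;
    arma::eig_sym(ev, V, arma::symmatu(T));  // ascending
    for (int a = 0; a < 3; ++a) {
      const int src = 2 - a;                 // descending order
      double lam = ev[src];
      if (lam < 0 && lam > -1e-10 * std::max(1.0, ev[2])) lam = 0.0;
      eval(i, a) = lam;
      arma::vec v = V.col(src);
      for (int c = 0; c < 3; ++c) {          // sign: first nonzero comp > 0
        if (std::abs(v[c]) > 1e-12) { if (v[c] < 0) v = -v; break; }
      }
      evec(i, 3 * a + 0) = v[0];
      evec(i, 3 * a + 1) = v[1];
      evec(i, 3 * a + 2) = v[2];
    }
  }
  return List::create(
    _["firstOrder"] = t1, _["secondOrder"] = t2,
    _["eigenvalues"] = eval, _["eigenvectors"] = evec,
    _["meanDist"] = meanDist,
    _["neighborCount"] = IntegerVector(cnt.begin(), cnt.end()),
    _["degenerate"] = degen);
}
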