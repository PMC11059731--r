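#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Online neural gas training pass. X: n x p data, W: k x p initial codebook
// (modified copy returned), pres: 1-based row indices of X in presentation
// order (length t_max = epochs * n). Step size and neighbourhood range decay
// exponentially on the presentation clock t = 1..t_max:
//   eps(t) = eps_i * (eps_f/eps_i)^(t/t_max),
//   lam(t) = lam_i * (lam_f/lam_i)^(t/t_max).
// Units are ranked by squared Euclidean distance to the presented sample,
// ties broken by lower unit index, and every unit moves by
//   w_i += eps(t) * exp(-rank_i / lam(t)) * (x - w_i).
// [[Rcpp::export]]
NumericMatrix ng_train_cpp(const NumericMatrix& X, const NumericMatrix& W0,
                           const IntegerVector& pres,
                           double eps_i, double eps_f,
                           double lam_i, double lam_f) {
  const int n = X.nrow(), p = X.ncol(), k = W0.nrow();
  if (W0.ncol() != p) stop("codebook/data dimension mismatch");
  NumericMatrix W = clone(W0);
  const double t_max = static_cast<double>(pres.size());
  std::vector<double> d2(k);
  std::vector<int> idx(k), rank(k);

  for (R_xlen_t t = 0; t < pres.size(); ++t) {
    const int xi = pres[t] - 1;
    if (xi < 0 || xi >= n) stop("presentation index out of range");
    const double frac = (t + 1.0) / t_max;
    const double eps = eps_i * std::pow(eps_f / eps_i, frac);
    const double lam = lam_i * std::pow(lam_f / lam_i, frac);

    for (int i = 0; i < k; ++i) {
      double s = 0.0;
      for (int j = 0; j < p; ++j) {
        const double d = X(xi, j) - W(i, j);
        s += d * d;
      }
      d2[i] = s;
      idx[i] = i;
    }
    std::stable_sort(idx.begin(), idx.end(),
                     [&](int a, int b) { return d2[a] < d2[b]; });
    for (int r = 0; r < k; ++r) rank[idx[r]] = r;

    for (int i = 0; i < k; ++i) {
      const double h = eps * std::exp(-rank[i] / lam);
      if (h <= 0.0) continue;
      for (int j = 0; j < p; ++j) {
        W(i, j) += h * (X(xi, j) - W(i, j));
      }
    }
  }
  return W;
}

// Mean Euclidean distance from each row of X to its nearest codebook row.
// [[Rcpp::export]]
double ng_quantization_error_cpp(const NumericMatrix& X,
                                 const NumericMatrix& W) {
  const int n = X.nrow(), p = X.ncol(), k = W.nrow();
  if (W.ncol() != p) stop("codebook/data dimension mismatch");
  double total = 0.0;
  for (int s = 0; s < n; ++s) {
    double best = R_PosInf;
    for (int i = 0; i < k; ++i) {
      double d2 = 0.0;
      for (int j = 0; j < p; ++j) {
        const double d = X(s, j) - W(i, j);
        d2 += d * d;
      }
      if (d2 < best) best = d2;
    }
    total += std::sqrt(best);
  }
  return total / n;
}
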