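// Fast kernels for the phylogenetic null models. The surrounding R code
// owns all randomization (permutations are generated in R so that seeds
// behave identically across platforms); these routines are deterministic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Per-sample mean nearest taxon distance.
// D: taxa x taxa patristic distances; X: samples x taxa abundances.
// Returns samples x 2 matrix: weighted MNTD, unweighted MNTD.
// Samples with fewer than two present taxa get NaN (caller validates).
// [[Rcpp::export]]
arma::mat cpp_mntd_all(const arma::mat& D, const arma::mat& X) {
  const arma::uword n = X.n_rows;
  arma::mat out(n, 2);
  out.fill(arma::datum::nan);
  for (arma::uword s = 0; s < n; ++s) {
    arma::uvec idx = arma::find(X.row(s).t() > 0);
    const arma::uword k = idx.n_elem;
    if (k < 2) continue;
    arma::vec ab = X.row(s).t();
    ab = ab.elem(idx);
    const double tot = arma::accu(ab);
    double wsum = 0.0, usum = 0.0;
    for (arma::uword a = 0; a < k; ++a) {
      double mn = arma::datum::inf;
      for (arma::uword b = 0; b < k; ++b) {
        if (a == b) continue;
        const double d = D(idx[a], idx[b]);
        if (d < mn) mn = d;
      }
      wsum += (ab[a] / tot) * mn;
      usum += mn;
    }
    out(s, 0) = wsum;
    out(s, 1) = usum / k;
  }
  return out;
}

// All-pairs abundance-weighted betaMNTD.
// D: taxa x taxa patristic distances; F: samples x taxa relative
// abundances (each row sums to 1 over its present taxa).
// betaMNTD(A,B) = 0.5 * [ sum_{i in A} f_iA min_{j in B} d(i,j)
//                       + sum_{j in B} f_jB min_{i in A} d(i,j) ].
// [[Rcpp::export]]
arma::mat cpp_bmntd_all(const arma::mat& D, const arma::mat& F) {
  const arma::uword n = F.n_rows;  // samples
  const arma::uword t = F.n_cols;  // taxa
  // M(i, s) = min over taxa j present in sample s of D(i, j)
  arma::mat M(t, n);
  for (arma::uword s = 0; s < n; ++s) {
    arma::uvec idx = arma::find(F.row(s).t() > 0);
    arma::mat sub = D.cols(idx);
    M.col(s) = arma::min(sub, 1);
  }
  arma::mat T = F * M;            // T(A,B) = sum_i f_iA * min_{j in B} d(i,j)
  arma::mat out = 0.5 * (T + T.t());
  out.diag().zeros();
  return out;
}

// All-pairs Bray-Curtis on a counts matrix (samples x taxa).
// [[Rcpp::export]]
arma::mat cpp_bray_all(const arma::mat& X) {
  const arma::uword n = X.n_rows;
  arma::vec tot = arma::sum(X, 1);
  arma::mat out(n, n, arma::fill::zeros);
  for (arma::uword a = 0; a < n; ++a) {
    for (arma::uword b = a + 1; b < n; ++b) {
      double mins = 0.0;
      for (arma::uword j = 0; j < X.n_cols; ++j)
        mins += std::min(X(a, j), X(b, j));
      const double d = 1.0 - 2.0 * mins / (tot[a] + tot[b]);
      out(a, b) = d;
      out(b, a) = d;
    }
  }
  return out;
}
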