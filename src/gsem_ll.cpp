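// Marginal (quadrature-integrated) log-likelihood of the latent-factor
// generalized SEM: J binary indicator items and D binary outcomes, all with
// logit links, sharing one standard-normal latent factor integrated out by
// Gauss-Hermite quadrature. Returns the weighted pseudo-log-likelihood,
// its analytic gradient, and optionally the per-unit score matrix used by
// the cluster-robust sandwich estimator.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double softplus(double x) {
  return x > 0 ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}

// [[Rcpp::export]]
Rcpp::List gsem_ll_cpp(const arma::vec& tau, const arma::vec& lambda,
                       const arma::vec& alpha, const Rcpp::List& beta,
                       const arma::vec& gamma,
                       const arma::mat& Y, const arma::mat& V,
                       const arma::mat& X, const Rcpp::List& xcols,
                       const arma::vec& w,
                       const arma::vec& nodes, const arma::vec& qw,
                       const bool want_grad, const bool want_scores) {
  const uword n = Y.n_rows, J = Y.n_cols, D = V.n_cols, K = nodes.n_elem;

  // indicator item log-probabilities per (item, node): the indicator linear
  // predictor has no covariates, so it is shared by all women
  mat lin_ind(J, K), l1p(J, K);
  for (uword k = 0; k < K; ++k) {
    for (uword j = 0; j < J; ++j) {
      double lp = tau(j) + lambda(j) * nodes(k);
      lin_ind(j, k) = lp;
      l1p(j, k) = -softplus(lp);  // log(1 - p_jk)
    }
  }
  // log f_ind(i,k) = sum_j y_ij*lin_jk + log(1-p_jk)
  mat ll = Y * (lin_ind);                       // n x K
  rowvec l1p_sum = sum(l1p, 0);
  ll.each_row() += l1p_sum;

  // outcome contributions
  mat etas(n, D);
  std::vector<uvec> idx(D);
  for (uword d = 0; d < D; ++d) {
    idx[d] = Rcpp::as<uvec>(xcols[d]);
    vec bd = Rcpp::as<vec>(beta[d]);
    etas.col(d) = alpha(d) + X.cols(idx[d]) * bd;
  }
  for (uword k = 0; k < K; ++k) {
    for (uword d = 0; d < D; ++d) {
      const double g = gamma(d) * nodes(k);
      for (uword i = 0; i < n; ++i) {
        const double lp = etas(i, d) + g;
        ll(i, k) += V(i, d) * lp - softplus(lp);
      }
    }
  }

  // log-sum-exp over nodes with quadrature weights
  ll.each_row() += log(qw).t();
  vec m = max(ll, 1);
  mat R = exp(ll.each_col() - m);               // unnormalized posteriors
  vec rs = sum(R, 1);
  vec li = m + log(rs);
  double loglik = dot(w, li);

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("loglik") = loglik);
  if (!want_grad && !want_scores) return out;

  R.each_col() /= rs;                           // posterior node weights
  mat WR = R.each_col() % w;                    // w_i * r_ik

  // measurement-part pieces
  mat P = 1.0 / (1.0 + exp(-lin_ind));          // J x K item probabilities
  uword p_len = 2 * J + 2 * D;
  for (uword d = 0; d < D; ++d) p_len += idx[d].n_elem;

  if (want_grad) {
    vec grad(p_len, fill::zeros);
    rowvec S = sum(WR, 0);                      // 1 x K
    mat T = Y.t() * WR;                         // J x K
    mat M = T - P.each_row() % S;               // J x K
    grad.subvec(0, J - 1) = sum(M, 1);
    grad.subvec(J, 2 * J - 1) = M * nodes;

    uword pos = 2 * J;
    uword gpos = p_len - D;
    for (uword d = 0; d < D; ++d) {
      // e_{ik} = w_i r_ik (v_id - p_idk)
      vec rs_e(n, fill::zeros);
      double dalpha = 0.0, dgamma = 0.0;
      for (uword k = 0; k < K; ++k) {
        const double g = gamma(d) * nodes(k);
        double colsum = 0.0;
        for (uword i = 0; i < n; ++i) {
          const double pdik = 1.0 / (1.0 + std::exp(-(etas(i, d) + g)));
          const double e = WR(i, k) * (V(i, d) - pdik);
          rs_e(i) += e;
          colsum += e;
        }
        dalpha += colsum;
        dgamma += colsum * nodes(k);
      }
      grad(pos) = dalpha;
      grad.subvec(pos + 1, pos + idx[d].n_elem) = X.cols(idx[d]).t() * rs_e;
      grad(gpos + d) = dgamma;
      pos += 1 + idx[d].n_elem;
    }
    out["grad"] = grad;
  }

  if (want_scores) {
    mat Sc(n, p_len, fill::zeros);
    // indicators: s_tau(i,j) = y_ij * w_i - (WR * P')_{ij}
    mat WP = WR * P.t();                        // n x J
    mat WPn = WR * (P.each_row() % nodes.t()).t();
    vec wr_nodes = WR * nodes;                  // n
    for (uword j = 0; j < J; ++j) {
      Sc.col(j) = Y.col(j) % w - WP.col(j);
      Sc.col(J + j) = Y.col(j) % wr_nodes - WPn.col(j);
    }
    uword pos = 2 * J;
    uword gpos = p_len - D;
    for (uword d = 0; d < D; ++d) {
      vec rs_e(n, fill::zeros), e_nodes(n, fill::zeros);
      for (uword k = 0; k < K; ++k) {
        const double g = gamma(d) * nodes(k);
        for (uword i = 0; i < n; ++i) {
          const double pdik = 1.0 / (1.0 + std::exp(-(etas(i, d) + g)));
          const double e = WR(i, k) * (V(i, d) - pdik);
          rs_e(i) += e;
          e_nodes(i) += e * nodes(k);
        }
      }
      Sc.col(pos) = rs_e;
      mat Xd = X.cols(idx[d]);
      Sc.cols(pos + 1, pos + idx[d].n_elem) = Xd.each_col() % rs_e;
      Sc.col(gpos + d) = e_nodes;
      pos += 1 + idx[d].n_elem;
    }
    out["scores"] = Sc;
  }
  return out;
}
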