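#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Gibbs sampler for y = mu + sum_k u_k + e with u_k = Phi_k delta_k,
// delta_k ~ N(0, sigma2_k I). Phi_k = U_k sqrt(D_k) from the eigen
// decomposition of the k-th record-level covariance kernel, so
// Phi_k' Phi_k = D_k is diagonal and each delta_k block is sampled jointly
// from its (diagonal-precision) full conditional. Missing responses are
// imputed by data augmentation each iteration. Variances get
// scaled-inverse-chi-square updates; R's RNG is used throughout so results
// are reproducible under set.seed().

static arma::vec rnorm_vec(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z[i] = R::norm_rand();
  return z;
}

// [[Rcpp::export(name = ".gibbs_core")]]
List gibbs_core(const arma::vec& y,
                const arma::uvec& is_obs,
                const List& Phi,
                const List& dvals,
                double df0,
                const arma::vec& S0,
                double S0e,
                int n_iter, int burn_in, int thin,
                bool update_var,
                const arma::vec& init_var,
                double init_var_e,
                const arma::uvec& genetic,
                bool store_gebv) {
  const int n = y.n_elem;
  const int K = Phi.size();

  std::vector<arma::mat> P(K);
  std::vector<arma::vec> d(K);
  for (int k = 0; k < K; ++k) {
    P[k] = as<arma::mat>(Phi[k]);
    d[k] = as<arma::vec>(dvals[k]);
  }

  arma::uvec obs_idx = arma::find(is_obs == 1);
  arma::uvec mis_idx = arma::find(is_obs == 0);
  const int n_obs = obs_idx.n_elem;
  if (n_obs < 2) stop("need at least 2 observed records");

  arma::vec y_cur = y;
  double mu = arma::mean(y.elem(obs_idx));
  for (arma::uword j = 0; j < mis_idx.n_elem; ++j) y_cur[mis_idx[j]] = mu;

  arma::vec sig2(K);
  double sig2e = update_var ? S0e : init_var_e;
  for (int k = 0; k < K; ++k) sig2[k] = update_var ? S0[k] : init_var[k];
  if (!update_var) sig2e = init_var_e;

  std::vector<arma::vec> delta(K), u(K);
  arma::vec sum_u(n, arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    delta[k] = arma::vec(P[k].n_cols, arma::fill::zeros);
    u[k] = arma::vec(n, arma::fill::zeros);
  }

  const int n_keep = (n_iter - burn_in + thin - 1) / thin;
  arma::mat samples(n_keep, K + 2, arma::fill::zeros);
  arma::mat u_mean(n, K, arma::fill::zeros);
  arma::vec eta_mean(n, arma::fill::zeros);
  arma::mat gebv_samples;
  if (store_gebv) gebv_samples.set_size(n_keep, n);

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    // data augmentation for masked records
    for (arma::uword j = 0; j < mis_idx.n_elem; ++j) {
      arma::uword i = mis_idx[j];
      y_cur[i] = mu + sum_u[i] + R::norm_rand() * std::sqrt(sig2e);
    }

    // overall mean, flat prior
    double rbar = arma::mean(y_cur - sum_u);
    mu = rbar + R::norm_rand() * std::sqrt(sig2e / n);

    // random-effect blocks
    for (int k = 0; k < K; ++k) {
      arma::vec r = y_cur - mu - sum_u + u[k];
      arma::vec c = P[k].t() * r;
      arma::vec prec = d[k] / sig2e + 1.0 / sig2[k];
      arma::vec m = (c / sig2e) / prec;
      delta[k] = m + rnorm_vec(P[k].n_cols) / arma::sqrt(prec);
      arma::vec u_new = P[k] * delta[k];
      sum_u += u_new - u[k];
      u[k] = u_new;
      if (update_var) {
        double ss = arma::dot(delta[k], delta[k]);
        sig2[k] = (df0 * S0[k] + ss) / R::rchisq(df0 + P[k].n_cols);
      }
    }

    if (update_var) {
      arma::vec e = y_cur - mu - sum_u;
      sig2e = (df0 * S0e + arma::dot(e, e)) / R::rchisq(df0 + n);
    }

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      for (int k = 0; k < K; ++k) samples(kept, k) = sig2[k];
      samples(kept, K) = sig2e;
      samples(kept, K + 1) = mu;
      arma::vec gebv(n, arma::fill::zeros);
      for (int k = 0; k < K; ++k) {
        u_mean.col(k) += u[k];
        if (genetic[k] == 1) gebv += u[k];
      }
      eta_mean += mu + sum_u;
      if (store_gebv) gebv_samples.row(kept) = gebv.t();
      ++kept;
    }
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
  }

  u_mean /= kept;
  eta_mean /= kept;

  return List::create(_["samples"] = samples.rows(0, kept - 1),
                      _["u_mean"] = u_mean,
                      _["eta_mean"] = eta_mean,
                      _["gebv_samples"] = store_gebv
                        ? wrap(gebv_samples.rows(0, kept - 1))
                        : R_NilValue,
                      _["n_kept"] = kept);
}
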