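// Gibbs/Metropolis sampler for the lambda-scaled phylogenetic regression and
// the posterior-predictive draw loop. All randomness goes through R's RNG so
// results are reproducible with set.seed() on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// V(lambda) = lambda * C off-diagonal, diagonal unchanged
static arma::mat lambda_vcv(const arma::mat& C, double lam) {
  arma::mat V = lam * C;
  V.diag() = C.diag();
  return V;
}

// reflect a proposal into [0, 1]
static double reflect01(double x) {
  while (x < 0.0 || x > 1.0) {
    if (x < 0.0) x = -x;
    if (x > 1.0) x = 2.0 - x;
  }
  return x;
}

// Cholesky with a tiny diagonal jitter fallback; returns false on failure
static bool chol_jitter(arma::mat& L, const arma::mat& V, int& jitter_events) {
  if (arma::chol(L, V, "lower")) return true;
  arma::mat Vj = V;
  Vj.diag() += 1e-10 * arma::mean(V.diag());
  ++jitter_events;
  return arma::chol(L, Vj, "lower");
}

// -1/2 log|V| - S/(2 sigma2) with S the V-inverse quadratic form of r
static double lam_logpost(const arma::mat& L, const arma::vec& r, double sigma2) {
  arma::vec z = arma::solve(arma::trimatl(L), r);
  double logdet = 2.0 * arma::sum(arma::log(L.diag()));
  return -0.5 * logdet - arma::dot(z, z) / (2.0 * sigma2);
}

// [[Rcpp::export]]
List mcmc_pgls_cpp(const arma::vec& y, const arma::mat& X, const List& Clist,
                   int burn_in, int n_iter, int thin,
                   double lambda_fixed, double lambda_init,
                   double prop_sd, bool adapt) {
  const int n = y.n_elem, p = X.n_cols, K = Clist.size();
  const bool estimate_lambda = lambda_fixed < 0.0;
  std::vector<arma::mat> C(K);
  for (int k = 0; k < K; ++k) C[k] = as<arma::mat>(Clist[k]);

  const int n_keep = n_iter / thin;
  arma::mat out_beta(n_keep, p);
  arma::vec out_sigma2(n_keep), out_lambda(n_keep);
  arma::ivec out_tree(n_keep), out_iter(n_keep);

  double lam = estimate_lambda ? lambda_init : lambda_fixed;
  int tree = 0, jitter_events = 0;
  long prop_count = 0, acc_count = 0;

  // initialise beta at the GLS solution and sigma2 at its ML value
  arma::mat L;
  if (!chol_jitter(L, lambda_vcv(C[0], lam), jitter_events))
    stop("initial covariance matrix is not positive definite");
  arma::mat W = arma::solve(arma::trimatl(L), X);
  arma::vec z = arma::solve(arma::trimatl(L), y);
  arma::vec beta = arma::solve(W.t() * W, W.t() * z);
  arma::vec resw = z - W * beta;
  double sigma2 = std::max(arma::dot(resw, resw) / n, 1e-12);

  const int total = burn_in + n_iter;
  int kept = 0;
  for (int it = 1; it <= total; ++it) {
    // tree identity: uniform over the supplied set each iteration
    tree = (int)std::floor(unif_rand() * K);
    if (tree >= K) tree = K - 1;

    arma::mat V = lambda_vcv(C[tree], lam);
    if (!chol_jitter(L, V, jitter_events))
      stop("covariance matrix not positive definite at iteration %d", it);
    W = arma::solve(arma::trimatl(L), X);
    z = arma::solve(arma::trimatl(L), y);

    // beta | sigma2, lambda, tree  ~  N(beta_hat, sigma2 * (X' V^-1 X)^-1)
    arma::mat A = W.t() * W;
    arma::vec bhat = arma::solve(A, W.t() * z);
    arma::mat U;
    if (!arma::chol(U, A, "upper")) stop("singular design in beta update");
    arma::vec eps(p);
    for (int j = 0; j < p; ++j) eps[j] = norm_rand();
    beta = bhat + std::sqrt(sigma2) * arma::solve(arma::trimatu(U), eps);

    // sigma2 | beta, lambda, tree  ~  Inv-Gamma(n/2, S/2) under the 1/sigma2 prior
    resw = z - W * beta;
    double S = arma::dot(resw, resw);
    double g = R::rgamma(n / 2.0, 2.0 / std::max(S, 1e-300));
    sigma2 = 1.0 / std::max(g, 1e-300);

    // lambda: Metropolis with a reflected Gaussian proposal on [0, 1]
    if (estimate_lambda) {
      double lam_new = reflect01(lam + prop_sd * norm_rand());
      arma::vec r = y - X * beta;
      double lp_old = lam_logpost(L, r, sigma2);
      arma::mat Lnew;
      bool accepted = false;
      if (chol_jitter(Lnew, lambda_vcv(C[tree], lam_new), jitter_events)) {
        double lp_new = lam_logpost(Lnew, r, sigma2);
        if (std::log(unif_rand()) < lp_new - lp_old) {
          lam = lam_new;
          L = Lnew;
          accepted = true;
        }
      }
      ++prop_count;
      if (accepted) ++acc_count;
      // scale adaptation during burn-in only; frozen afterwards
      if (adapt && it <= burn_in) {
        prop_sd *= std::exp(0.05 * ((accepted ? 1.0 : 0.0) - 0.3));
        prop_sd = std::min(std::max(prop_sd, 0.01), 1.0);
      }
    }

    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      out_beta.row(kept) = beta.t();
      out_sigma2[kept] = sigma2;
      out_lambda[kept] = lam;
      out_tree[kept] = tree + 1;
      out_iter[kept] = it;
      ++kept;
    }
  }

  return List::create(
    _["beta"] = out_beta, _["sigma2"] = out_sigma2, _["lambda"] = out_lambda,
    _["tree_index"] = out_tree, _["iteration"] = out_iter,
    _["accept_rate"] = prop_count > 0 ? (double)acc_count / prop_count : NA_REAL,
    _["prop_sd_final"] = prop_sd, _["jitter_events"] = jitter_events);
}

// One predictive draw per posterior sample from the conditional Gaussian of
// the focal tip given the observed tips.
// [[Rcpp::export]]
List predict_draws_cpp(const arma::mat& beta, const arma::vec& sigma2,
                       const arma::vec& lambda, const arma::ivec& tree_index,
                       const List& Cobs_list, const List& cf_list,
                       const arma::vec& vff, const arma::vec& y,
                       const arma::mat& X, const arma::vec& xf) {
  const int m = beta.n_rows, K = Cobs_list.size();
  std::vector<arma::mat> C(K);
  std::vector<arma::vec> cf(K);
  for (int k = 0; k < K; ++k) {
    C[k] = as<arma::mat>(Cobs_list[k]);
    cf[k] = as<arma::vec>(cf_list[k]);
  }
  arma::vec draws(m), means(m), vars(m);
  int n_clipped = 0, jitter_events = 0;

  for (int i = 0; i < m; ++i) {
    const int k = tree_index[i] - 1;
    const double lam = lambda[i];
    arma::mat L;
    if (!chol_jitter(L, lambda_vcv(C[k], lam), jitter_events))
      stop("observed-tip covariance not positive definite in prediction");
    arma::vec cfl = lam * cf[k];  // focal covariances are off-diagonal terms
    arma::vec r = y - X * beta.row(i).t();
    arma::vec zr = arma::solve(arma::trimatl(L), r);
    arma::vec zc = arma::solve(arma::trimatl(L), cfl);
    double mu = arma::dot(xf, beta.row(i).t()) + arma::dot(zc, zr);
    double v = sigma2[i] * (vff[k] - arma::dot(zc, zc));
    if (v < 1e-12) { v = 1e-12; ++n_clipped; }
    means[i] = mu;
    vars[i] = v;
    draws[i] = mu + std::sqrt(v) * norm_rand();
  }
  return List::create(_["draws"] = draws, _["mean"] = means, _["var"] = vars,
                      _["n_clipped"] = n_clipped,
                      _["jitter_events"] = jitter_events);
}
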