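// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Ridge-penalised logistic regression without intercept, solved by Newton's
// method with step halving.  The objective is the Bernoulli log-likelihood
// minus lambda * ||w||^2 (lambda is the total penalty, already scaled by the
// caller).  No intercept: the discriminator output y = w'x is a signed
// evidence amplitude whose zero marks the face/car decision boundary.

static double penalised_ll(const arma::mat& X, const arma::vec& z,
                           const arma::vec& w, double lambda) {
  arma::vec eta = X * w;
  // log(1 + exp(eta)) computed stably
  arma::vec lse(eta.n_elem);
  for (arma::uword i = 0; i < eta.n_elem; i++) {
    double e = eta[i];
    lse[i] = e > 0 ? e + std::log1p(std::exp(-e)) : std::log1p(std::exp(e));
  }
  return arma::dot(z, eta) - arma::accu(lse) - lambda * arma::dot(w, w);
}

static arma::vec newton_logistic(const arma::mat& X, const arma::vec& z,
                                 double lambda, double tol, int maxit,
                                 const arma::vec& w0, bool* converged) {
  arma::uword K = X.n_cols;
  arma::vec w = w0;
  double ll = penalised_ll(X, z, w, lambda);
  *converged = false;
  for (int it = 0; it < maxit; it++) {
    arma::vec eta = X * w;
    arma::vec p = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec grad = X.t() * (z - p) - 2.0 * lambda * w;
    if (arma::norm(grad, 2) < tol) { *converged = true; break; }
    arma::vec wvar = p % (1.0 - p);
    arma::mat H = X.t() * (X.each_col() % wvar);
    H.diag() += 2.0 * lambda;
    arma::vec step;
    bool ok = arma::solve(step, H, grad, arma::solve_opts::likely_sympd);
    if (!ok) { step = grad / (arma::norm(grad, 2) + 1.0); }
    // step halving to guarantee ascent
    double alpha_step = 1.0;
    for (int h = 0; h < 30; h++) {
      arma::vec w_new = w + alpha_step * step;
      double ll_new = penalised_ll(X, z, w_new, lambda);
      if (ll_new >= ll - 1e-12) { w = w_new; ll = ll_new; break; }
      alpha_step *= 0.5;
    }
  }
  (void)K;
  return w;
}

//' @noRd
// [[Rcpp::export]]
List ridge_logistic_cpp(const arma::mat& X, const arma::vec& z,
                        double lambda, double tol, int maxit) {
  bool conv = false;
  arma::vec w0(X.n_cols, arma::fill::zeros);
  arma::vec w = newton_logistic(X, z, lambda, tol, maxit, w0, &conv);
  arma::vec eta = X * w;
  arma::vec p = 1.0 / (1.0 + arma::exp(-eta));
  arma::vec grad = X.t() * (z - p) - 2.0 * lambda * w;
  return List::create(_["w"] = w,
                      _["converged"] = conv,
                      _["grad_norm"] = arma::norm(grad, 2),
                      _["loglik"] = penalised_ll(X, z, w, 0.0));
}

//' @noRd
// [[Rcpp::export]]
List loo_window_cpp(const arma::mat& X, const arma::ivec& trial,
                    const arma::vec& z_trial, double lambda, double tol,
                    int maxit) {
  // X stacks all within-window samples (rows) over trials; `trial` gives the
  // 1-based trial index of each row.  For each held-out trial the model is
  // refit on all other rows (warm-started at the full-data solution) and the
  // held-out amplitude is the mean discriminator output over its rows.
  int n_trials = z_trial.n_elem;
  arma::uword N = X.n_rows;

  // expand labels to rows
  arma::vec z_row(N);
  for (arma::uword r = 0; r < N; r++) z_row[r] = z_trial[trial[r] - 1];

  bool conv = false;
  arma::vec w0(X.n_cols, arma::fill::zeros);
  arma::vec w_full = newton_logistic(X, z_row, lambda, tol, maxit, w0, &conv);

  // row index lists per trial
  std::vector<std::vector<arma::uword> > rows(n_trials);
  for (arma::uword r = 0; r < N; r++) rows[trial[r] - 1].push_back(r);

  arma::vec y_loo(n_trials);
  for (int i = 0; i < n_trials; i++) {
    arma::uvec keep(N - rows[i].size());
    arma::uword k = 0;
    for (arma::uword r = 0; r < N; r++)
      if (trial[r] - 1 != i) keep[k++] = r;
    arma::mat Xi = X.rows(keep);
    arma::vec zi = z_row.elem(keep);
    bool ci = false;
    arma::vec wi = newton_logistic(Xi, zi, lambda, tol, maxit, w_full, &ci);
    double s = 0.0;
    for (arma::uword r : rows[i]) s += arma::dot(X.row(r), wi);
    y_loo[i] = s / rows[i].size();
  }

  // full-data training amplitudes (per-trial mean of w'x)
  arma::vec y_train(n_trials, arma::fill::zeros);
  arma::vec eta = X * w_full;
  for (arma::uword r = 0; r < N; r++) y_train[trial[r] - 1] += eta[r];
  for (int i = 0; i < n_trials; i++) y_train[i] /= rows[i].size();

  return List::create(_["y_loo"] = y_loo,
                      _["y_train"] = y_train,
                      _["w"] = w_full,
                      _["converged"] = conv);
}
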