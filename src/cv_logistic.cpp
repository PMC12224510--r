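// Ridge-penalized logistic regression (IRLS) and repeated stratified
// cross-validated AUC evaluation. These are the inner loops of the
// composite-biomarker search: thousands of candidate feature subsets, each
// refit on every training fold of every CV repeat, so they live in C++.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Mann-Whitney AUC with ties counted half, via mean ranks.
static double auc_rank(const arma::vec& scores, const arma::uvec& y) {
  const arma::uword n = scores.n_elem;
  arma::uvec ord = arma::stable_sort_index(scores);
  arma::vec ranks(n);
  arma::uword i = 0;
  while (i < n) {
    arma::uword j = i;
    while (j + 1 < n && scores(ord(j + 1)) == scores(ord(i))) ++j;
    double mean_rank = 0.5 * (static_cast<double>(i) + static_cast<double>(j)) + 1.0;
    for (arma::uword t = i; t <= j; ++t) ranks(ord(t)) = mean_rank;
    i = j + 1;
  }
  double n1 = 0, rank_sum = 0;
  for (arma::uword t = 0; t < n; ++t) {
    if (y(t) == 1) { n1 += 1.0; rank_sum += ranks(t); }
  }
  double n0 = static_cast<double>(n) - n1;
  if (n1 == 0 || n0 == 0) return NA_REAL;
  return (rank_sum - n1 * (n1 + 1.0) / 2.0) / (n1 * n0);
}

// IRLS for logistic regression with ridge penalty on the slopes (intercept
// unpenalized). X has no intercept column; returns (intercept, slopes).
// maxit is deliberately modest: on separable folds the penalized optimum
// has large but finite coefficients and the held-out ranking (all that AUC
// needs) stabilizes within a few iterations.
static arma::vec ridge_logistic(const arma::mat& X, const arma::vec& y,
                                double lambda, int maxit = 12,
                                double tol = 1e-6) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  arma::mat Xd(n, p + 1, arma::fill::ones);
  if (p > 0) Xd.cols(1, p) = X;
  arma::vec beta(p + 1, arma::fill::zeros);
  arma::mat pen(p + 1, p + 1, arma::fill::zeros);
  for (arma::uword j = 1; j <= p; ++j) pen(j, j) = lambda;
  for (int it = 0; it < maxit; ++it) {
    arma::vec eta = Xd * beta;
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w = mu % (1.0 - mu);
    w.transform([](double v) { return v < 1e-10 ? 1e-10 : v; });
    arma::vec z = eta + (y - mu) / w;
    arma::mat XtW = Xd.t();
    XtW.each_row() %= w.t();
    arma::vec beta_new;
    bool ok = arma::solve(beta_new, XtW * Xd + pen, XtW * z,
                          arma::solve_opts::likely_sympd);
    if (!ok) break;
    double step = arma::norm(beta_new - beta, "inf");
    beta = beta_new;
    if (step < tol) break;
  }
  return beta;
}

// [[Rcpp::export(name = ".ridge_logistic_cpp")]]
NumericVector ridge_logistic_cpp(const arma::mat& X, const arma::vec& y,
                                 double lambda) {
  return wrap(ridge_logistic(X, y, lambda));
}

// [[Rcpp::export(name = ".auc_cpp")]]
double auc_cpp(const arma::vec& scores, const IntegerVector& labels) {
  arma::uvec y(labels.size());
  for (int i = 0; i < labels.size(); ++i) y(i) = labels[i];
  return auc_rank(scores, y);
}

// Fold-level AUCs for one feature subset. folds: n x repeats matrix of fold
// ids (1..k). Columns of X are standardized by training-fold mean/sd;
// zero-variance training columns are zeroed out.
static arma::vec cv_fold_aucs(const arma::mat& X, const arma::vec& y,
                              const arma::imat& folds, int k, double lambda) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  const arma::uword R = folds.n_cols;
  arma::vec out(R * static_cast<arma::uword>(k));
  arma::uvec yu(n);
  for (arma::uword i = 0; i < n; ++i) yu(i) = y(i) > 0.5 ? 1 : 0;
  arma::uword pos = 0;
  for (arma::uword r = 0; r < R; ++r) {
    for (int f = 1; f <= k; ++f) {
      arma::uvec test_idx = arma::find(folds.col(r) == f);
      arma::uvec train_idx = arma::find(folds.col(r) != f);
      arma::mat Xtr = X.rows(train_idx);
      arma::mat Xte = X.rows(test_idx);
      arma::rowvec mu = arma::mean(Xtr, 0);
      arma::rowvec sg = arma::stddev(Xtr, 0, 0);
      for (arma::uword j = 0; j < p; ++j) {
        if (sg(j) > 0) {
          Xtr.col(j) = (Xtr.col(j) - mu(j)) / sg(j);
          Xte.col(j) = (Xte.col(j) - mu(j)) / sg(j);
        } else {
          Xtr.col(j).zeros();
          Xte.col(j).zeros();
        }
      }
      arma::vec beta = ridge_logistic(Xtr, y.elem(train_idx), lambda);
      arma::vec scores(Xte.n_rows, arma::fill::value(beta(0)));
      if (p > 0) scores += Xte * beta.subvec(1, p);
      out(pos++) = auc_rank(scores, yu.elem(test_idx));
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cv_fold_aucs_cpp")]]
NumericVector cv_fold_aucs_cpp(const arma::mat& X, const arma::vec& y,
                               const arma::imat& folds, int k, double lambda) {
  return wrap(cv_fold_aucs(X, y, folds, k, lambda));
}

// Evaluate many candidate feature subsets in one call. candidates: max_dim x
// n_candidates matrix of 1-based column indices into Xall, 0-padded.
// Returns n_candidates x 2 matrix (auc_mean, auc_sd over fold-level AUCs).
// [[Rcpp::export(name = ".cv_eval_many_cpp")]]
NumericMatrix cv_eval_many_cpp(const arma::mat& Xall, const arma::vec& y,
                               const IntegerMatrix& candidates,
                               const arma::imat& folds, int k, double lambda) {
  const int ncand = candidates.ncol();
  NumericMatrix res(ncand, 2);
  for (int c = 0; c < ncand; ++c) {
    std::vector<arma::uword> ids;
    for (int r = 0; r < candidates.nrow(); ++r) {
      if (candidates(r, c) > 0) ids.push_back(candidates(r, c) - 1);
    }
    arma::uvec cols(ids);
    arma::vec aucs = cv_fold_aucs(Xall.cols(cols), y, folds, k, lambda);
    res(c, 0) = arma::mean(aucs);
    res(c, 1) = arma::stddev(aucs);
    if (c % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return res;
}
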