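// PLS1 (single-response NIPALS) kernel and cross-validated prediction paths.
//
// BOSS scores ~1000 bootstrap submodels per shrinkage iteration, each by
// K-fold cross-validation over a grid of component counts, so the inner
// fit/predict loop is compiled. The pure-R fitPLS() implements the same
// algorithm and is held equal to this kernel by tests.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double EPS = 1e-12;

// Column means / sample (n-1) sds; zero-variance columns get sd = 1 so the
// centred column scales to exactly 0 (and thus receives coefficient 0).
static void autoscale_params(const mat& X, rowvec& mu, rowvec& sdv) {
  mu = mean(X, 0);
  sdv = stddev(X, 0, 0);  // norm_type 0 -> divides by n-1
  sdv.elem(find(sdv < EPS)).fill(1.0);
}

// NIPALS PLS1 on already-scaled data. Returns p x Amax coefficient path on
// the scaled scale; column a-1 is the a-component regression vector. If the
// response deflates to zero before Amax components, remaining columns repeat
// the last informative one.
static mat pls1_coef_path(mat X, vec y, int Amax) {
  const uword p = X.n_cols;
  mat W(p, Amax, fill::zeros), P(p, Amax, fill::zeros);
  vec q(Amax, fill::zeros);
  mat B(p, Amax, fill::zeros);
  int a_eff = 0;
  for (int a = 0; a < Amax; ++a) {
    vec w = X.t() * y;
    double nw = norm(w, 2);
    if (nw < EPS) break;
    w /= nw;
    vec t = X * w;
    double tt = dot(t, t);
    if (tt < EPS) break;
    vec pl = X.t() * t / tt;
    double ql = dot(y, t) / tt;
    X -= t * pl.t();
    y -= ql * t;
    W.col(a) = w;
    P.col(a) = pl;
    q(a) = ql;
    a_eff = a + 1;
    mat PtW = P.cols(0, a).t() * W.cols(0, a);  // upper-triangular, unit diag
    B.col(a) = W.cols(0, a) * solve(trimatu(PtW), q.subvec(0, a));
  }
  if (a_eff == 0) return B;  // X'y == 0: null model, all-zero coefficients
  for (int a = a_eff; a < Amax; ++a) B.col(a) = B.col(a_eff - 1);
  return B;
}

// [[Rcpp::export]]
arma::mat cpp_pls_coef_path(const arma::mat& X, const arma::vec& y, int Amax,
                            bool autoscale) {
  if (Amax < 1) Rcpp::stop("Amax must be >= 1");
  if (!autoscale) return pls1_coef_path(X, y, Amax);
  rowvec mu, sdv;
  autoscale_params(X, mu, sdv);
  mat Xs = X.each_row() - mu;
  Xs.each_row() /= sdv;
  double ym = mean(y), ys = stddev(y, 0);
  if (ys < EPS) ys = 1.0;
  vec yv = (y - ym) / ys;
  return pls1_coef_path(Xs, yv, Amax);
}

// Shared CV engine: held-out predictions for component counts 1..Amax.
static mat cv_prediction_path(const mat& X, const vec& y,
                              const ivec& fold_labels, int Amax,
                              bool per_fold_scale) {
  const uword n = X.n_rows;
  const int K = fold_labels.max();
  mat preds(n, Amax, fill::zeros);

  rowvec mu_g, sd_g;
  double ym_g = 0, ys_g = 1;
  if (!per_fold_scale) {
    autoscale_params(X, mu_g, sd_g);
    ym_g = mean(y);
    ys_g = stddev(y, 0);
    if (ys_g < EPS) ys_g = 1.0;
  }

  for (int k = 1; k <= K; ++k) {
    uvec test = find(fold_labels == k);
    uvec train = find(fold_labels != k);
    if (test.n_elem == 0) continue;
    if (train.n_elem < 2) Rcpp::stop("training fold must have >= 2 samples");
    mat Xtr = X.rows(train);
    vec ytr = y.elem(train);

    rowvec mu, sdv;
    double ym, ys;
    if (per_fold_scale) {
      autoscale_params(Xtr, mu, sdv);
      ym = mean(ytr);
      ys = stddev(ytr, 0);
      if (ys < EPS) ys = 1.0;
    } else {
      mu = mu_g; sdv = sd_g; ym = ym_g; ys = ys_g;
    }
    Xtr.each_row() -= mu;
    Xtr.each_row() /= sdv;
    vec ytr_s = (ytr - ym) / ys;

    int A_k = std::min<int>(Amax, std::min<uword>(train.n_elem - 1, X.n_cols));
    mat B = pls1_coef_path(Xtr, ytr_s, A_k);

    mat Xte = X.rows(test);
    Xte.each_row() -= mu;
    Xte.each_row() /= sdv;
    mat yh = Xte * B;
    for (int a = 0; a < Amax; ++a) {
      int col = std::min(a, A_k - 1);
      preds.submat(test, uvec{(uword)a}) = ym + ys * yh.col(col);
    }
  }
  return preds;
}

// Score one bootstrap subset per column of `draws` (1-based column indices
// into X, duplicates allowed): deduplicate the draws, cross-validate a PLS
// submodel with automatic component selection (minimum pooled MSEP, ties to
// the smaller count), and return per subset its RMSECV, component count and
// deduplicated support. The hot loop of a BOSS iteration.
// [[Rcpp::export]]
Rcpp::List cpp_boss_score_subsets(const arma::mat& X, const arma::vec& y,
                                  const arma::ivec& fold_labels,
                                  const arma::imat& draws, int Amax_cfg,
                                  bool per_fold_scale) {
  const int S = draws.n_cols;
  const uword n = X.n_rows;
  ivec tab(fold_labels.max(), fill::zeros);
  for (uword i = 0; i < n; ++i) tab(fold_labels(i) - 1)++;
  const int min_train = n - tab.max();

  Rcpp::NumericVector rmsecv(S);
  Rcpp::IntegerVector ncomp(S), sizes(S);
  Rcpp::List subsets(S);
  for (int s = 0; s < S; ++s) {
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
    ivec col = draws.col(s);
    uvec idx = arma::sort(arma::unique(arma::conv_to<uvec>::from(col))) - 1;
    mat Xs = X.cols(idx);
    int Amax = std::min<int>(Amax_cfg, std::min<int>(idx.n_elem, min_train - 1));
    if (Amax < 1) Amax = 1;
    mat preds = cv_prediction_path(Xs, y, fold_labels, Amax, per_fold_scale);
    int best_a = 0;
    double best_msep = datum::inf;
    for (int a = 0; a < Amax; ++a) {
      double msep = accu(square(y - preds.col(a))) / n;
      if (msep < best_msep - 0.0) {  // strict: ties keep the smaller count
        best_msep = msep;
        best_a = a;
      }
    }
    rmsecv[s] = std::sqrt(best_msep);
    ncomp[s] = best_a + 1;
    sizes[s] = idx.n_elem;
    std::vector<int> sub1 = arma::conv_to<std::vector<int>>::from(idx + 1);
    subsets[s] = Rcpp::IntegerVector(sub1.begin(), sub1.end());
  }
  return Rcpp::List::create(Rcpp::Named("rmsecv") = rmsecv,
                            Rcpp::Named("ncomp") = ncomp,
                            Rcpp::Named("size") = sizes,
                            Rcpp::Named("subsets") = subsets);
}

// Held-out predictions (raw response scale) for every component count
// 1..Amax under K-fold CV. fold_labels are 1..K. When per_fold_scale, the
// autoscaling parameters are refit on each training fold (no leakage);
// otherwise they come from the full data (the "global" scaling variant).
// [[Rcpp::export]]
arma::mat cpp_cv_prediction_path(const arma::mat& X, const arma::vec& y,
                                 const arma::ivec& fold_labels, int Amax,
                                 bool per_fold_scale) {
  if (y.n_elem != X.n_rows) Rcpp::stop("X and y dimensions differ");
  if (fold_labels.n_elem != X.n_rows)
    Rcpp::stop("fold labels length must equal n");
  return cv_prediction_path(X, y, fold_labels, Amax, per_fold_scale);
}
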