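// PLS1 (single-response partial least squares) core: NIPALS with deflation,
// returning the regression-coefficient path for all component counts up to
// max_lv, plus a leave-one-out PRESS curve. Kept in C++ because nested
// cross-validation (outer LOO x inner LOO per fold) refits the model
// O(n^2) times.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Coefficient path on already standardized X / centered y.
// Returns p x max_lv matrix; if the response deflates to numerical zero
// before max_lv components, later columns repeat the converged solution.
static mat pls1_coef_path(const mat &X, const vec &y, const int max_lv) {
  const uword p = X.n_cols;
  mat W(p, max_lv, fill::zeros), P(p, max_lv, fill::zeros);
  vec q(max_lv, fill::zeros);
  mat Xd = X;
  vec yd = y;
  int used = 0;
  for (int a = 0; a < max_lv; ++a) {
    vec w = Xd.t() * yd;
    double nw = norm(w);
    if (nw < 1e-14) break;
    w /= nw;
    vec t = Xd * w;
    double tt = dot(t, t);
    if (tt < 1e-28) break;
    vec pv = Xd.t() * t / tt;
    double qa = dot(yd, t) / tt;
    Xd -= t * pv.t();
    yd -= qa * t;
    W.col(a) = w;
    P.col(a) = pv;
    q(a) = qa;
    ++used;
  }
  mat B(p, max_lv, fill::zeros);
  for (int a = 0; a < max_lv; ++a) {
    int m = std::min(a + 1, used);
    if (m == 0) continue;
    mat R = P.cols(0, m - 1).t() * W.cols(0, m - 1);
    vec b = W.cols(0, m - 1) * solve(R, q.subvec(0, m - 1));
    B.col(a) = b;
  }
  return B;
}

// Column means / sds (denominator n - 1, matching R's sd()).
static void col_stats(const mat &X, rowvec &mu, rowvec &sd) {
  mu = mean(X, 0);
  sd = stddev(X, 0, 0);  // norm_type 0 -> n - 1
}

// [[Rcpp::export(name = ".cpp_pls1_path")]]
arma::mat cpp_pls1_path(const arma::mat &X, const arma::vec &y, int max_lv) {
  rowvec mu, sd;
  col_stats(X, mu, sd);
  if (any(sd < 1e-12)) Rcpp::stop("constant feature column");
  mat Xs = X.each_row() - mu;
  Xs.each_row() /= sd;
  vec yc = y - mean(y);
  return pls1_coef_path(Xs, yc, max_lv);
}

// Leave-one-out PRESS curve: PRESS(k) = sum_i (y_i - yhat_{-i,k})^2 for
// k = 1..max_lv. Standardization parameters are recomputed from each
// training fold, exactly as a naive refit-per-subject loop would.
// [[Rcpp::export(name = ".cpp_press_curve")]]
arma::vec cpp_press_curve(const arma::mat &X, const arma::vec &y, int max_lv) {
  const uword n = X.n_rows;
  vec press(max_lv, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    uvec idx = regspace<uvec>(0, n - 1);
    idx.shed_row(i);
    mat Xt = X.rows(idx);
    vec yt = y(idx);
    rowvec mu, sd;
    col_stats(Xt, mu, sd);
    if (any(sd < 1e-12)) Rcpp::stop("constant feature column in a training fold");
    mat Xs = Xt.each_row() - mu;
    Xs.each_row() /= sd;
    double ym = mean(yt);
    mat B = pls1_coef_path(Xs, yt - ym, max_lv);
    rowvec xs = (X.row(i) - mu) / sd;
    for (int k = 0; k < max_lv; ++k) {
      double pred = ym + dot(xs, B.col(k));
      double e = y(i) - pred;
      press(k) += e * e;
    }
  }
  return press;
}
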