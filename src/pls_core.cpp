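// NIPALS PLS2 and the nested leave-one-out machinery.
//
// The double cross-validation re-fits a PLS-DA model n*(n-1) times per run
// (and the permutation test repeats the whole procedure per permutation),
// so the inner loops live here rather than in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// NIPALS PLS2: X (n x p) scaled, Y (n x q) centered. X is deflated per
// component, Y is not. Components stop early if the X residual is exhausted.
struct NipalsFit {
  mat W, P, T, Q;  // p x A, p x A, n x A, q x A
  int ncomp;
};

NipalsFit nipals(mat X, const mat& Y, int ncomp, double tol = 1e-12,
                 int maxiter = 500) {
  const uword n = X.n_rows, p = X.n_cols, q = Y.n_cols;
  ncomp = std::min<int>(ncomp, std::min(n, p));
  NipalsFit f;
  f.W.set_size(p, ncomp);
  f.P.set_size(p, ncomp);
  f.T.set_size(n, ncomp);
  f.Q.set_size(q, ncomp);
  int a = 0;
  for (; a < ncomp; ++a) {
    if (norm(X, "fro") < 1e-10) break;
    // start from the Y column with the largest sum of squares
    uword start;
    rowvec ss = sum(square(Y), 0);
    ss.max(start);
    vec u = Y.col(start);
    vec t_old(n, fill::zeros), w(p), t(n), qa(q);
    for (int it = 0; it < maxiter; ++it) {
      w = X.t() * u;
      double wn = norm(w);
      if (wn < 1e-14) break;
      w /= wn;
      t = X * w;
      double tt = dot(t, t);
      if (tt < 1e-14) break;
      qa = Y.t() * t / tt;
      double qq = dot(qa, qa);
      if (qq < 1e-14) break;
      u = Y * qa / qq;
      if (norm(t - t_old) / (norm(t) + 1e-30) < tol) break;
      t_old = t;
    }
    double tt = dot(t, t);
    if (tt < 1e-14) break;
    vec pa = X.t() * t / tt;
    X -= t * pa.t();
    f.W.col(a) = w;
    f.P.col(a) = pa;
    f.T.col(a) = t;
    f.Q.col(a) = qa;
  }
  f.ncomp = a;
  f.W.resize(p, a);
  f.P.resize(p, a);
  f.T.resize(n, a);
  f.Q.resize(q, a);
  return f;
}

// B_a = W_a (P_a' W_a)^-1 Q_a'  for the leading a components
mat pls_B(const NipalsFit& f, int a) {
  mat Wa = f.W.cols(0, a - 1);
  mat Pa = f.P.cols(0, a - 1);
  mat Qa = f.Q.cols(0, a - 1);
  return Wa * solve(Pa.t() * Wa, Qa.t());
}

// argmax with ties resolved to the earliest index
uword argmax_first(const rowvec& v) {
  uword best = 0;
  for (uword k = 1; k < v.n_elem; ++k)
    if (v(k) > v(best)) best = k;
  return best;
}

// column means / sample SDs (n-1); zero-SD columns get scale 1 so the
// centered column is identically zero and attracts no PLS weight
void scale_params(const mat& X, rowvec& m, rowvec& s) {
  m = mean(X, 0);
  s = stddev(X, 0, 0);
  s.elem(find(s < 1e-12)).ones();
}

// inner LOO misclassification counts for each component count 1..a_max
ivec inner_errs(const mat& Xtr, const mat& Ytr, int a_max) {
  const uword n1 = Xtr.n_rows;
  ivec errs(a_max, fill::zeros);
  for (uword j = 0; j < n1; ++j) {
    mat Xin = Xtr, Yin = Ytr;
    Xin.shed_row(j);
    Yin.shed_row(j);
    if (any(sum(Yin, 0) == 0))
      Rcpp::stop("inner training fold %d lost an entire class", (int)j + 1);
    rowvec m, s;
    scale_params(Xin, m, s);
    mat Xs = (Xin.each_row() - m).each_row() / s;
    rowvec ym = mean(Yin, 0);
    mat Yc = Yin.each_row() - ym;
    NipalsFit f = nipals(Xs, Yc, a_max);
    rowvec xnew = (Xtr.row(j) - m) / s;
    uword truth = argmax_first(Ytr.row(j));
    uword last_pred = 0;
    // score the held-out sample through the deflation sequence: with a
    // components, yhat = ym + sum_{k<=a} t_k q_k' where t_k = x_defl . w_k
    // (identical to the closed-form B route, but O(p) per component)
    rowvec x = xnew, yhat = ym;
    for (int a = 1; a <= a_max; ++a) {
      if (a <= f.ncomp) {
        double tnew = dot(x, f.W.col(a - 1));
        x -= tnew * f.P.col(a - 1).t();
        yhat += tnew * f.Q.col(a - 1).t();
        last_pred = argmax_first(yhat);
      }
      // a beyond the achievable rank keeps the deepest model's prediction
      if (last_pred != truth) errs(a - 1) += 1;
    }
  }
  return errs;
}

int select_a(const ivec& errs) {
  int best = 0;
  for (uword a = 1; a < errs.n_elem; ++a)
    if (errs(a) < errs(best)) best = a;  // strict: ties keep the smaller a
  return best + 1;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_nipals")]]
Rcpp::List cpp_nipals(const arma::mat& X, const arma::mat& Y, int ncomp,
                      double tol, int maxiter) {
  NipalsFit f = nipals(X, Y, ncomp, tol, maxiter);
  mat B = (f.ncomp > 0) ? pls_B(f, f.ncomp)
                        : mat(X.n_cols, Y.n_cols, fill::zeros);
  return Rcpp::List::create(
      Rcpp::Named("weights") = f.W, Rcpp::Named("loadings") = f.P,
      Rcpp::Named("scores") = f.T, Rcpp::Named("y_loadings") = f.Q,
      Rcpp::Named("coefficients") = B, Rcpp::Named("ncomp") = f.ncomp);
}

// [[Rcpp::export(name = ".cpp_inner_errs")]]
arma::ivec cpp_inner_errs(const arma::mat& Xtr, const arma::mat& Ytr,
                          int a_max) {
  return inner_errs(Xtr, Ytr, a_max);
}

// Full double cross-validation: outer LOO over samples; per outer fold an
// inner LOO picks the component count; scaling is recomputed on every
// training portion and applied to its held-out sample.
// [[Rcpp::export(name = ".cpp_double_cv")]]
Rcpp::List cpp_double_cv(const arma::mat& X, const arma::mat& Yind,
                         int a_max) {
  const uword n = X.n_rows, p = X.n_cols, q = Yind.n_cols;
  ivec sel(n);
  uvec pred(n);
  mat yhat(n, q);
  cube B(p, q, n);
  for (uword i = 0; i < n; ++i) {
    mat Xtr = X, Ytr = Yind;
    Xtr.shed_row(i);
    Ytr.shed_row(i);
    if (any(sum(Ytr, 0) == 0))
      Rcpp::stop("outer fold %d (sample left out) lost an entire class",
                 (int)i + 1);
    int a_eff = std::min<int>(a_max, std::min<uword>(Xtr.n_rows - 2, p));
    if (a_eff < 1) Rcpp::stop("too few samples for inner cross-validation");
    ivec errs = inner_errs(Xtr, Ytr, a_eff);
    int a_sel = select_a(errs);
    rowvec m, s;
    scale_params(Xtr, m, s);
    mat Xs = (Xtr.each_row() - m).each_row() / s;
    rowvec ym = mean(Ytr, 0);
    NipalsFit f = nipals(Xs, Ytr.each_row() - ym, a_sel);
    int a_use = std::max(f.ncomp, 1);
    mat Bi = (f.ncomp > 0) ? pls_B(f, a_use) : mat(p, q, fill::zeros);
    rowvec xnew = (X.row(i) - m) / s;
    rowvec yh = xnew * Bi + ym;
    sel(i) = a_sel;
    yhat.row(i) = yh;
    pred(i) = argmax_first(yh) + 1;  // 1-based class index
    B.slice(i) = Bi;
  }
  return Rcpp::List::create(
      Rcpp::Named("ncomp_selected") = sel, Rcpp::Named("predicted") = pred,
      Rcpp::Named("y_predicted") = yhat, Rcpp::Named("coefficients") = B);
}
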