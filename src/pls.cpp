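// Numerical kernels: PLS1 (NIPALS with X- and y-deflation), cross-validated
// RMSECV over a column subset, and a cyclic coordinate-descent LASSO path.
// Everything here is deterministic; all randomness (fold assignment,
// bootstraps, chromosomes) is drawn on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Pls1Fit {
  mat W, P, T;     // weights, X-loadings, scores
  vec q;           // y-loadings
  rowvec xMeans;
  double yMean;
  int ncomp;       // components actually extracted
};

// PLS1: for univariate y the NIPALS inner loop converges in a single step,
// so each component is extracted directly (w = X'y normalised).
Pls1Fit pls1_core(const mat& X, const vec& y, int A) {
  const uword n = X.n_rows, p = X.n_cols;
  Pls1Fit f;
  f.xMeans = mean(X, 0);
  f.yMean = mean(y);
  mat E = X.each_row() - f.xMeans;
  vec r = y - f.yMean;

  A = std::min<int>(A, std::min<uword>(n - 1, p));
  f.W.set_size(p, A); f.P.set_size(p, A); f.T.set_size(n, A); f.q.set_size(A);

  int a = 0;
  for (; a < A; ++a) {
    vec w = E.t() * r;
    double nw = norm(w, 2);
    if (nw < 1e-12) break;           // residual X carries no covariance left
    w /= nw;
    vec t = E * w;
    double tt = dot(t, t);
    if (tt < 1e-12) break;
    vec pl = E.t() * t / tt;
    double qa = dot(r, t) / tt;
    E -= t * pl.t();
    r -= qa * t;
    f.W.col(a) = w; f.P.col(a) = pl; f.T.col(a) = t; f.q(a) = qa;
  }
  f.ncomp = a;
  if (a < A) { f.W.resize(p, a); f.P.resize(p, a); f.T.resize(n, a); f.q.resize(a); }
  return f;
}

// Regression coefficients for each truncation k = 1..ncomp:
// B_k = W_k (P_k' W_k)^{-1} q_k.
mat coef_path(const Pls1Fit& f) {
  const int A = f.ncomp;
  mat B(f.W.n_rows, std::max(A, 1), fill::zeros);
  if (A == 0) return B;
  mat PW = f.P.t() * f.W;
  for (int k = 1; k <= A; ++k) {
    vec s = solve(PW.submat(0, 0, k - 1, k - 1), f.q.subvec(0, k - 1));
    B.col(k - 1) = f.W.cols(0, k - 1) * s;
  }
  return B;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_pls1(const arma::mat& X, const arma::vec& y, int ncomp) {
  Pls1Fit f = pls1_core(X, y, ncomp);
  mat B = coef_path(f);
  vec intercepts(std::max(f.ncomp, 1), fill::value(f.yMean));
  for (int k = 0; k < f.ncomp; ++k)
    intercepts(k) = f.yMean - as_scalar(f.xMeans * B.col(k));
  return Rcpp::List::create(
    Rcpp::Named("weights") = f.W,
    Rcpp::Named("loadings") = f.P,
    Rcpp::Named("scores") = f.T,
    Rcpp::Named("yLoadings") = f.q,
    Rcpp::Named("xMeans") = f.xMeans.t(),
    Rcpp::Named("yMean") = f.yMean,
    Rcpp::Named("coefPath") = B,
    Rcpp::Named("intercepts") = intercepts,
    Rcpp::Named("ncomp") = f.ncomp);
}

// RMSECV(k), k = 1..kmax, for PLS1 on X[, idx] with a fixed fold assignment.
// idx is 1-based; foldid holds fold labels 1..F per sample. When a training
// fold supports fewer than k components the deepest available model is used.
// [[Rcpp::export]]
arma::vec cpp_pls_cv(const arma::mat& X, const arma::vec& y,
                     const arma::uvec& idx, const arma::ivec& foldid,
                     int kmax) {
  mat Xs = X.cols(idx - 1);
  const uword n = Xs.n_rows;
  const int F = foldid.max();
  vec sse(kmax, fill::zeros);

  for (int f = 1; f <= F; ++f) {
    uvec te = find(foldid == f);
    if (te.n_elem == 0) continue;
    uvec tr = find(foldid != f);
    Pls1Fit fit = pls1_core(Xs.rows(tr), y(tr), kmax);
    mat B = coef_path(fit);
    mat Xte = Xs.rows(te);
    Xte.each_row() -= fit.xMeans;
    for (int k = 1; k <= kmax; ++k) {
      int kk = std::min(k, std::max(fit.ncomp, 1));
      vec pred = Xte * B.col(kk - 1) + fit.yMean;
      vec err = y(te) - pred;
      sse(k - 1) += dot(err, err);
    }
  }
  return sqrt(sse / double(n));
}

// Raw-scale coefficients (and intercept) of a k-component PLS1 model on
// X[, idx]; used by BOSS for its |beta| weight updates.
// [[Rcpp::export]]
Rcpp::List cpp_pls_coef(const arma::mat& X, const arma::vec& y,
                        const arma::uvec& idx, int k) {
  mat Xs = X.cols(idx - 1);
  Pls1Fit f = pls1_core(Xs, y, k);
  mat B = coef_path(f);
  int kk = std::max(std::min(k, f.ncomp), 1);
  vec beta = f.ncomp == 0 ? vec(Xs.n_cols, fill::zeros) : vec(B.col(kk - 1));
  double intercept = f.yMean - as_scalar(f.xMeans * beta);
  return Rcpp::List::create(Rcpp::Named("beta") = beta,
                            Rcpp::Named("intercept") = intercept,
                            Rcpp::Named("ncomp") = f.ncomp);
}

namespace {
inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}
} // namespace

// Coordinate descent for (1/2n)||y - X b||^2 + lambda ||b||_1 along a
// decreasing lambda path with warm starts. X must have centred columns of
// unit (1/n) variance and y must be centred. Returns p x L coefficients.
// Convergence is declared on the relative decrease of the penalised
// objective: with nearly collinear columns (adjacent wavenumber channels)
// the split of a coefficient between twins converges arbitrarily slowly
// while the objective — and hence fit and support structure — converges
// fast, so a coefficient-change criterion would spin without profit.
// [[Rcpp::export]]
arma::mat cpp_lasso_path(const arma::mat& X, const arma::vec& y,
                         const arma::vec& lambda, double tol, int maxit) {
  const uword n = X.n_rows, p = X.n_cols, L = lambda.n_elem;
  vec beta(p, fill::zeros);
  vec r = y;
  mat out(p, L, fill::zeros);

  auto pass = [&](const uvec& cols, double lam) {
    for (uword ci = 0; ci < cols.n_elem; ++ci) {
      const uword j = cols(ci);
      const double bj = beta(j);
      const double z = dot(X.col(j), r) / double(n) + bj;
      const double bn = soft(z, lam);
      if (bn != bj) {
        r -= (bn - bj) * X.col(j);
        beta(j) = bn;
      }
    }
  };
  auto objective = [&](double lam) {
    return 0.5 * dot(r, r) / double(n) + lam * norm(beta, 1);
  };

  const uvec all = regspace<uvec>(0, p - 1);
  for (uword l = 0; l < L; ++l) {
    const double lam = lambda(l);
    int iter = 0;
    double objPrev = objective(lam);
    while (iter < maxit) {
      pass(all, lam);              // full sweep: picks up new actives
      ++iter;
      double obj = objective(lam);
      bool done = objPrev - obj <= tol * std::max(obj, 1e-12);
      objPrev = obj;
      if (done) break;
      while (iter < maxit) {       // then iterate the active set only
        uvec act = find(abs(beta) > 0);
        if (act.n_elem == 0) break;
        pass(act, lam);
        ++iter;
        obj = objective(lam);
        bool flat = objPrev - obj <= tol * std::max(obj, 1e-12);
        objPrev = obj;
        if (flat) break;
      }
    }
    out.col(l) = beta;
  }
  return out;
}
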