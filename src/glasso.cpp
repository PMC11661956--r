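// Graphical LASSO: L1-penalized sparse inverse covariance estimation by
// block coordinate descent (one lasso regression per column, itself solved
// by coordinate descent). Operates on a correlation/covariance matrix S.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft_threshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Lasso sub-problem: minimise 0.5 * b' V b - s' b + rho * ||b||_1.
// V is (p-1)x(p-1) positive definite; warm-started from b.
static void lasso_cd(const mat& V, const vec& s, double rho, vec& b,
                     double tol, int maxit) {
  const uword q = s.n_elem;
  for (int it = 0; it < maxit; ++it) {
    double delta = 0.0;
    for (uword k = 0; k < q; ++k) {
      double old = b(k);
      // partial residual: s_k - sum_{l != k} V_kl * b_l
      double r = s(k) - dot(V.row(k), b) + V(k, k) * old;
      double bk = soft_threshold(r, rho) / V(k, k);
      b(k) = bk;
      delta = std::max(delta, std::fabs(bk - old));
    }
    if (delta < tol) break;
  }
}

// [[Rcpp::export(name = ".glasso_cpp")]]
Rcpp::List glasso_cpp(const arma::mat& S, double rho,
                      double tol = 1e-6, int maxit = 200,
                      Rcpp::Nullable<Rcpp::NumericMatrix> W_init = R_NilValue,
                      Rcpp::Nullable<Rcpp::NumericMatrix> B_init = R_NilValue) {
  const uword p = S.n_rows;
  // diagonal left unpenalized: a correlation input keeps its unit diagonal
  mat W = S;
  mat B(p - 1 < 1 ? 1 : p - 1, p, fill::zeros);  // lasso coefs per column
  if (B_init.isNotNull()) {
    mat B0 = Rcpp::as<mat>(Rcpp::NumericMatrix(B_init.get()));
    if (B0.n_rows == B.n_rows && B0.n_cols == B.n_cols) B = B0;
  }
  if (W_init.isNotNull()) {
    mat W0 = Rcpp::as<mat>(Rcpp::NumericMatrix(W_init.get()));
    if (W0.n_rows == p && W0.n_cols == p) {
      W = W0;
      W.diag() = S.diag();   // the diagonal is fixed by the input
    }
  }

  if (p == 1) {
    mat Wout(1, 1); Wout(0, 0) = S(0, 0) + rho;
    mat Th(1, 1); Th(0, 0) = 1.0 / Wout(0, 0);
    return Rcpp::List::create(Rcpp::Named("w") = Wout,
                              Rcpp::Named("theta") = Th,
                              Rcpp::Named("b") = B,
                              Rcpp::Named("iterations") = 0,
                              Rcpp::Named("converged") = true);
  }

  // convergence threshold relative to the mean absolute off-diagonal of S
  const double offdiag_scale =
      (accu(abs(S)) - accu(abs(S.diag()))) / std::max(1.0, double(p * (p - 1)));
  const double outer_tol = tol * std::max(offdiag_scale, 1e-12);
  bool converged = false;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    double max_change = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx = regspace<uvec>(0, p - 1);
      idx.shed_row(j);
      mat W11 = W(idx, idx);
      vec s12 = S.col(j);
      s12.shed_row(j);
      vec b = B.col(j);
      lasso_cd(W11, s12, rho, b, tol * 0.1, 200);
      B.col(j) = b;
      vec w12 = W11 * b;
      for (uword k = 0; k < idx.n_elem; ++k) {
        double change = std::fabs(W(idx(k), j) - w12(k));
        if (change > max_change) max_change = change;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
    }
    if (max_change < outer_tol) { converged = true; break; }
  }

  // recover the precision matrix from W and the lasso coefficients
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    uvec idx = regspace<uvec>(0, p - 1);
    idx.shed_row(j);
    vec b = B.col(j);
    vec w12 = W(idx, uvec{j});
    double th22 = 1.0 / (W(j, j) - dot(w12, b));
    Theta(j, j) = th22;
    for (uword k = 0; k < idx.n_elem; ++k) {
      double v = -b(k) * th22;
      Theta(idx(k), j) = v;
    }
  }
  Theta = 0.5 * (Theta + Theta.t());   // symmetrise numerical asymmetry

  return Rcpp::List::create(Rcpp::Named("w") = W,
                            Rcpp::Named("theta") = Theta,
                            Rcpp::Named("b") = B,
                            Rcpp::Named("iterations") = it + 1,
                            Rcpp::Named("converged") = converged);
}
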