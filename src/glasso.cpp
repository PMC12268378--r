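// Block coordinate descent for the L1-penalized Gaussian precision matrix
// (graphical lasso). Off-diagonal penalty only; stops on the duality gap.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
Rcpp::List glasso_fit_cpp(const arma::mat& S, double lambda, arma::mat B,
                          double tol, int max_sweeps) {
  const int p = S.n_rows;
  arma::mat W = S;
  arma::mat Theta(p, p, arma::fill::zeros);
  bool converged = false;
  int sweeps = 0;

  for (int s = 0; s < max_sweeps && !converged; ++s) {
    for (int j = 0; j < p; ++j) {
      arma::uvec idx(p - 1);
      int t = 0;
      for (int i = 0; i < p; ++i) if (i != j) idx[t++] = i;
      arma::mat W11 = W.submat(idx, idx);
      arma::vec s12 = S.col(j);
      s12 = s12.elem(idx);
      arma::vec beta = B.col(j);
      for (int inner = 0; inner < 100; ++inner) {
        double delta = 0.0;
        for (int k = 0; k < p - 1; ++k) {
          double r = s12[k] - arma::dot(W11.row(k).t(), beta) +
            W11(k, k) * beta[k];
          double a = std::abs(r) - lambda;
          double b = a > 0 ? (r > 0 ? a : -a) / W11(k, k) : 0.0;
          delta = std::max(delta, std::abs(b - beta[k]));
          beta[k] = b;
        }
        if (delta < tol * 1e-2) break;
      }
      B.col(j) = beta;
      arma::vec w12 = W11 * beta;
      t = 0;
      for (int i = 0; i < p; ++i) if (i != j) {
        W(i, j) = w12[t];
        W(j, i) = w12[t];
        ++t;
      }
    }
    // recover Theta column-wise from (W, B)
    for (int j = 0; j < p; ++j) {
      double dot = 0.0;
      int t = 0;
      for (int i = 0; i < p; ++i) if (i != j) { dot += W(i, j) * B(t, j); ++t; }
      double t22 = 1.0 / (W(j, j) - dot);
      Theta(j, j) = t22;
      t = 0;
      for (int i = 0; i < p; ++i) if (i != j) { Theta(i, j) = -B(t, j) * t22; ++t; }
    }
    Theta = (Theta + Theta.t()) / 2.0;
    double gap = arma::accu(S % Theta) - p +
      lambda * (arma::accu(arma::abs(Theta)) -
                arma::accu(arma::abs(Theta.diag())));
    sweeps = s + 1;
    if (std::isfinite(gap) && std::abs(gap) < tol) converged = true;
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = W, Rcpp::Named("Theta") = Theta,
    Rcpp::Named("B") = B, Rcpp::Named("sweeps") = sweeps,
    Rcpp::Named("converged") = converged);
}
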