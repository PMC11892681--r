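// Exact t-SNE (quadratic, for subsampled pixel sets) and nearest-neighbour
// out-of-sample placement. Deterministic: initial coordinates are supplied
// by the caller (PCA initialisation), no RNG inside.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Conditional probabilities with per-point bandwidth calibrated to a target
// perplexity by bisection on log-precision.
static mat perplexity_probs(const mat& D2, double perplexity) {
  const uword n = D2.n_rows;
  mat P(n, n, fill::zeros);
  const double logU = std::log(perplexity);
  for (uword i = 0; i < n; ++i) {
    double beta = 1.0, betamin = -datum::inf, betamax = datum::inf;
    rowvec Di = D2.row(i);
    Di(i) = 0.0;  // self term excluded below; keep finite so H stays finite
    rowvec Pi;
    for (int iter = 0; iter < 60; ++iter) {
      Pi = exp(-Di * beta);
      Pi(i) = 0.0;
      double sumP = accu(Pi);
      if (sumP <= 0) sumP = datum::eps;
      double H = std::log(sumP) + beta * accu(Di % Pi) / sumP;
      Pi /= sumP;
      double diff = H - logU;
      if (std::abs(diff) < 1e-5) break;
      if (diff > 0) { betamin = beta; beta = std::isinf(betamax) ? beta * 2 : (beta + betamax) / 2; }
      else          { betamax = beta; beta = std::isinf(betamin) ? beta / 2 : (beta + betamin) / 2; }
    }
    P.row(i) = Pi;
  }
  return P;
}

// [[Rcpp::export]]
arma::mat cpp_tsne(const arma::mat& X, const arma::mat& Y0, double perplexity,
                   int n_iter, double learning_rate, double exaggeration,
                   int exaggeration_iter) {
  const uword n = X.n_rows;
  // pairwise squared distances in feature space
  colvec sx = sum(square(X), 1);
  mat D2 = repmat(sx, 1, n) + repmat(sx.t(), n, 1) - 2.0 * (X * X.t());
  D2.elem(find(D2 < 0)).zeros();

  mat P = perplexity_probs(D2, perplexity);
  P = (P + P.t());
  P /= std::max(accu(P), datum::eps);
  P.elem(find(P < 1e-12)).fill(1e-12);

  mat Y = Y0, dY(n, Y0.n_cols, fill::zeros), gains(n, Y0.n_cols, fill::ones);
  double momentum = 0.5;
  mat Pe = P * exaggeration;

  for (int iter = 0; iter < n_iter; ++iter) {
    const mat& Puse = (iter < exaggeration_iter) ? Pe : P;
    colvec sy = sum(square(Y), 1);
    mat num = repmat(sy, 1, n) + repmat(sy.t(), n, 1) - 2.0 * (Y * Y.t());
    num = 1.0 / (1.0 + num);
    num.diag().zeros();
    mat Q = num / std::max(accu(num), datum::eps);
    Q.elem(find(Q < 1e-12)).fill(1e-12);

    mat L = (Puse - Q) % num;
    mat grad = 4.0 * (diagmat(sum(L, 1)) - L) * Y;

    // delta-bar-delta gains as in the reference implementation
    umat same = (sign(grad) == sign(dY));
    gains.elem(find(same == 0)) += 0.2;
    gains.elem(find(same == 1)) *= 0.8;
    gains.elem(find(gains < 0.01)).fill(0.01);

    dY = momentum * dY - learning_rate * (gains % grad);
    Y += dY;
    Y.each_row() -= mean(Y, 0);
    if (iter == 250) momentum = 0.8;
  }
  return Y;
}

// Index (1-based) of the nearest row of `fitted` for each row of `query`.
// [[Rcpp::export]]
arma::uvec cpp_nearest_neighbour(const arma::mat& fitted, const arma::mat& query) {
  const uword nf = fitted.n_rows, nq = query.n_rows;
  colvec f2 = sum(square(fitted), 1);
  uvec out(nq);
  const uword block = 4096;
  for (uword s = 0; s < nq; s += block) {
    uword e = std::min(s + block, nq) - 1;
    mat Qb = query.rows(s, e);
    mat D = repmat(f2, 1, Qb.n_rows) - 2.0 * (fitted * Qb.t());
    for (uword j = 0; j < Qb.n_rows; ++j) out(s + j) = D.col(j).index_min() + 1;
  }
  return out;
}
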