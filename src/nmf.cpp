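#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Multiplicative-update NMF (Frobenius loss), Lee & Seung updates.
// W, H are modified from the supplied (deterministic) initialization.
// Convergence is checked every `check_every` iterations on the relative
// change of the reconstruction error.
// [[Rcpp::export(name = ".nmf_mu_cpp")]]
Rcpp::List nmf_mu_cpp(const arma::mat& A, arma::mat W, arma::mat H,
                      const int max_iter, const double tol,
                      const int check_every = 10) {
  const double eps = 1e-10;
  const double a_norm = norm(A, "fro");
  double err_prev = datum::inf;
  double err = datum::inf;
  int iters = 0;

  for (int it = 1; it <= max_iter; ++it) {
    // H <- H * (W'A) / (W'W H)
    H %= (W.t() * A) / (W.t() * W * H + eps);
    // W <- W * (A H') / (W H H')
    W %= (A * H.t()) / (W * (H * H.t()) + eps);
    iters = it;
    if (it % check_every == 0 || it == max_iter) {
      err = norm(A - W * H, "fro");
      double denom = (a_norm > 0.0) ? a_norm : 1.0;
      if (std::abs(err_prev - err) / denom < tol) break;
      err_prev = err;
    }
  }
  if (!std::isfinite(err)) err = norm(A - W * H, "fro");

  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("H") = H,
                            Rcpp::Named("frobenius_error") = err,
                            Rcpp::Named("iterations") = iters);
}
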