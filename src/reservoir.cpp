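#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Sequential leaky-ESN state recursion:
//   r'(t) = f(Win * u(t) + W * r(t-1) + b)
//   r(t)  = alpha * r'(t) + (1 - alpha) * r(t-1)        (standard)
//   r(t)  = alpha * r'(t) + (1 - alpha) * W * r(t-1)    (printed variant)
// u is the already input-scaled series (T x Nx), row-per-step.
// f is tanh (linearAct = false) or the identity (diagnostic mode).
// [[Rcpp::export]]
arma::mat reservoir_states_cpp(const arma::mat& u, const arma::mat& W,
                               const arma::mat& Win, double alpha,
                               double bias, const arma::vec& r0,
                               bool printedLeak, bool linearAct) {
  const arma::uword T = u.n_rows, Nr = W.n_rows;
  arma::mat states(T, Nr);
  arma::vec r = r0;
  for (arma::uword t = 0; t < T; ++t) {
    arma::vec Wr = W * r;
    arma::vec pre = Win * u.row(t).t() + Wr;
    pre += bias;
    arma::vec rp = linearAct ? pre : arma::tanh(pre);
    r = alpha * rp + (1.0 - alpha) * (printedLeak ? Wr : r);
    states.row(t) = r.t();
  }
  return states;
}
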