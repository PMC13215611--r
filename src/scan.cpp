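#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Gated diagonal state-space scan over time-major batched activations.
// U is (T*B) x F with row (t-1)*B + b holding trial b at time t.
// h_t = alpha (*) h_{t-1} + (1 - alpha) (*) u_t, h_0 = 0 (per feature).

// [[Rcpp::export]]
arma::mat scan_forward_cpp(const arma::mat& U, const arma::vec& alpha,
                           int B) {
  const int TB = U.n_rows, F = U.n_cols, T = TB / B;
  mat H(TB, F);
  rowvec a = alpha.t();
  rowvec one_m_a = 1.0 - a;
  mat h(B, F, fill::zeros);
  for (int t = 0; t < T; ++t) {
    const int r0 = t * B;
    mat u_t = U.rows(r0, r0 + B - 1);
    h.each_row() %= a;
    u_t.each_row() %= one_m_a;
    h += u_t;
    H.rows(r0, r0 + B - 1) = h;
  }
  return H;
}

// Backward pass of the scan. Given dL/dH, returns dL/dU and dL/dalpha.
// g_t = dH_t + alpha (*) g_{t+1}; dU_t = (1 - alpha) (*) g_t;
// dalpha_f = sum_t g_t (*) (h_{t-1} - u_t), with h_0 = 0.

// [[Rcpp::export]]
Rcpp::List scan_backward_cpp(const arma::mat& dH, const arma::mat& H,
                             const arma::mat& U, const arma::vec& alpha,
                             int B) {
  const int TB = U.n_rows, F = U.n_cols, T = TB / B;
  mat dU(TB, F);
  rowvec a = alpha.t();
  rowvec one_m_a = 1.0 - a;
  rowvec dalpha(F, fill::zeros);
  mat g(B, F, fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    const int r0 = t * B;
    g.each_row() %= a;
    g += dH.rows(r0, r0 + B - 1);
    mat du_t = g;
    du_t.each_row() %= one_m_a;
    dU.rows(r0, r0 + B - 1) = du_t;
    mat diff = -U.rows(r0, r0 + B - 1);
    if (t > 0) diff += H.rows(r0 - B, r0 - 1);
    dalpha += sum(g % diff, 0);
  }
  return Rcpp::List::create(Rcpp::Named("dU") = dU,
                            Rcpp::Named("dalpha") = dalpha.t());
}
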