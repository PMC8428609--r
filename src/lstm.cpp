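// Single-layer LSTM cell: full forward pass with cached gate activations,
// and exact backpropagation through time. Gate block order in W/U/b rows is
// [input; forget; cell; output], each `hidden` rows. Matrices are row-per-step.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::mat& X, const arma::mat& W,
                            const arma::mat& U, const arma::vec& b,
                            const arma::vec& h0, const arma::vec& c0) {
  const uword T = X.n_rows;
  const uword H = U.n_cols;
  mat Hs(T, H), Cs(T, H), I(T, H), F(T, H), G(T, H), O(T, H), Tc(T, H);
  vec h = h0, c = c0;
  for (uword t = 0; t < T; ++t) {
    vec z = W * X.row(t).t() + U * h + b;
    vec i = 1.0 / (1.0 + exp(-z.subvec(0, H - 1)));
    vec f = 1.0 / (1.0 + exp(-z.subvec(H, 2 * H - 1)));
    vec g = tanh(z.subvec(2 * H, 3 * H - 1));
    vec o = 1.0 / (1.0 + exp(-z.subvec(3 * H, 4 * H - 1)));
    c = f % c + i % g;
    vec tc = tanh(c);
    h = o % tc;
    Hs.row(t) = h.t(); Cs.row(t) = c.t(); Tc.row(t) = tc.t();
    I.row(t) = i.t(); F.row(t) = f.t(); G.row(t) = g.t(); O.row(t) = o.t();
  }
  return Rcpp::List::create(
    Rcpp::Named("H") = Hs, Rcpp::Named("C") = Cs, Rcpp::Named("I") = I,
    Rcpp::Named("F") = F, Rcpp::Named("G") = G, Rcpp::Named("O") = O,
    Rcpp::Named("Tc") = Tc, Rcpp::Named("h_last") = h,
    Rcpp::Named("c_last") = c);
}

// dH: per-step gradient w.r.t. hidden outputs; dh_last/dc_last: gradients
// flowing into the final states from downstream (zero vectors if none).
// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::mat& X, const arma::mat& W,
                             const arma::mat& U, const arma::vec& h0,
                             const arma::vec& c0, const arma::mat& Hs,
                             const arma::mat& Cs, const arma::mat& I,
                             const arma::mat& F, const arma::mat& G,
                             const arma::mat& O, const arma::mat& Tc,
                             const arma::mat& dH, const arma::vec& dh_last,
                             const arma::vec& dc_last) {
  const uword T = X.n_rows;
  const uword H = U.n_cols;
  const uword D = X.n_cols;
  mat dW(4 * H, D, fill::zeros), dU(4 * H, H, fill::zeros), dX(T, D);
  vec db(4 * H, fill::zeros);
  vec dh_next = dh_last, dc_next = dc_last;
  for (uword t = T; t-- > 0;) {
    vec dh = dH.row(t).t() + dh_next;
    vec i = I.row(t).t(), f = F.row(t).t(), g = G.row(t).t(), o = O.row(t).t();
    vec tc = Tc.row(t).t();
    vec c_prev = (t == 0) ? c0 : Cs.row(t - 1).t();
    vec h_prev = (t == 0) ? h0 : Hs.row(t - 1).t();
    vec d_o = dh % tc;
    vec dc = dc_next + dh % o % (1.0 - tc % tc);
    vec d_i = dc % g;
    vec d_g = dc % i;
    vec d_f = dc % c_prev;
    dc_next = dc % f;
    vec dz(4 * H);
    dz.subvec(0, H - 1)         = d_i % i % (1.0 - i);
    dz.subvec(H, 2 * H - 1)     = d_f % f % (1.0 - f);
    dz.subvec(2 * H, 3 * H - 1) = d_g % (1.0 - g % g);
    dz.subvec(3 * H, 4 * H - 1) = d_o % o % (1.0 - o);
    dW += dz * X.row(t);
    dU += dz * h_prev.t();
    db += dz;
    dX.row(t) = (W.t() * dz).t();
    dh_next = U.t() * dz;
  }
  return Rcpp::List::create(
    Rcpp::Named("dW") = dW, Rcpp::Named("dU") = dU, Rcpp::Named("db") = db,
    Rcpp::Named("dX") = dX, Rcpp::Named("dh0") = dh_next,
    Rcpp::Named("dc0") = dc_next);
}
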