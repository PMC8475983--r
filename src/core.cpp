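// Hot loops for the rate-network simulator and the temporally restricted
// FORCE trainer.  All randomness stays on the R side: these routines are
// deterministic functions of their inputs, so seed reproducibility is
// inherited from R's RNG.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Forward Euler integration of
//   tau * dx/dt = -x + (J + Wf Wo^T + Wfd Wd^T) r + Wi u,   r = tanh(x).
// The low-rank terms are applied as feedback of the scalar readout z_o and
// the 2-d latent readout z_d, never by forming the dense N x N sum.
//
// Step convention: x stored at row t is the state after t Euler updates
// from x0; recorded r, z_o, z_d are computed from that same state.
// [[Rcpp::export]]
Rcpp::List sim_core(const arma::mat& J, const arma::mat& Wi,
                    const arma::vec& Wf, const arma::mat& Wfd,
                    const arma::vec& Wo, const arma::mat& Wd,
                    const arma::mat& u, const arma::vec& x0,
                    double dt, double tau) {
  const uword N = J.n_rows;
  const uword T = u.n_cols;
  mat X(T, N), R(T, N), ZD(T, 2);
  vec ZO(T);
  vec x = x0;
  const double h = dt / tau;
  for (uword t = 0; t < T; ++t) {
    vec r = tanh(x);
    double zo = dot(Wo, r);
    vec zd = Wd.t() * r;
    x += h * (-x + J * r + Wf * zo + Wfd * zd + Wi * u.col(t));
    if (!x.is_finite())
      Rcpp::stop("state overflow: non-finite x at step %d", (int)(t + 1));
    vec rt = tanh(x);
    X.row(t) = x.t();
    R.row(t) = rt.t();
    ZO(t) = dot(Wo, rt);
    ZD.row(t) = (Wd.t() * rt).t();
  }
  return Rcpp::List::create(Rcpp::Named("x") = X, Rcpp::Named("r") = R,
                            Rcpp::Named("z_o") = ZO, Rcpp::Named("z_d") = ZD);
}

// One training trial: simulate step by step and apply recursive
// least-squares updates to the readouts inside the error kernel only.
//
// ep[t] codes the epoch of step t: 0 = unconstrained, 1 = delay (latent
// target fd.col(t) active, update Wd/Pd), 2 = response (target fo, update
// Wo/Po).  A running counter over kernel steps implements the update
// cadence, giving exactly floor(|Td u Tr| / update_every) update events.
//
// RLS, per update event with rate vector r:
//   P' = P - (P r)(P r)^T / (1 + r^T P r)       (so P' r = P r / denom)
//   W' = W - e * P' r
// Pd is shared by the two columns of Wd; Po serves Wo.
// [[Rcpp::export]]
Rcpp::List train_core(const arma::mat& J, const arma::mat& Wi,
                      const arma::vec& Wf, const arma::mat& Wfd,
                      arma::vec Wo, arma::mat Wd,
                      arma::mat Po, arma::mat Pd,
                      const arma::mat& u, const arma::ivec& ep,
                      const arma::mat& fd, double fo,
                      const arma::vec& x0, double dt, double tau,
                      int update_every) {
  const uword T = u.n_cols;
  vec ZO(T);
  mat ZD(T, 2);
  vec x = x0;
  const double h = dt / tau;
  int kcount = 0, nupd = 0;
  std::vector<int> upd_step;
  std::vector<double> e_pre, e_post;
  for (uword t = 0; t < T; ++t) {
    vec r = tanh(x);
    double zo = dot(Wo, r);
    vec zd = Wd.t() * r;
    x += h * (-x + J * r + Wf * zo + Wfd * zd + Wi * u.col(t));
    if (!x.is_finite())
      Rcpp::stop("state overflow: non-finite x at step %d", (int)(t + 1));
    vec rt = tanh(x);
    double zo_t = dot(Wo, rt);
    vec zd_t = Wd.t() * rt;
    ZO(t) = zo_t;
    ZD.row(t) = zd_t.t();
    int code = ep(t);
    if (code > 0) {
      ++kcount;
      if (kcount % update_every == 0) {
        if (code == 1) {
          vec Pr = Pd * rt;
          double denom = 1.0 + dot(rt, Pr);
          Pd -= (Pr * Pr.t()) / denom;
          vec K = Pr / denom;  // = Pd' * rt
          vec e2 = zd_t - fd.col(t);
          Wd -= K * e2.t();
        } else {
          vec Pr = Po * rt;
          double denom = 1.0 + dot(rt, Pr);
          Po -= (Pr * Pr.t()) / denom;
          vec K = Pr / denom;
          double e = zo_t - fo;
          Wo -= e * K;
          upd_step.push_back((int)(t + 1));
          e_pre.push_back(std::abs(e));
          e_post.push_back(std::abs(dot(Wo, rt) - fo));
        }
        ++nupd;
      }
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("W_o") = Wo, Rcpp::Named("W_d") = Wd,
      Rcpp::Named("P_o") = Po, Rcpp::Named("P_d") = Pd,
      Rcpp::Named("x_final") = x, Rcpp::Named("z_o") = ZO,
      Rcpp::Named("z_d") = ZD, Rcpp::Named("n_updates") = nupd,
      Rcpp::Named("update_step") = upd_step,
      Rcpp::Named("e_pre") = e_pre, Rcpp::Named("e_post") = e_post);
}
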