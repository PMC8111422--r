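// Hot loops of the calibration machinery: nonlinear rollout with adjoint
// backprop, and per-condition Gauss-Newton accumulation with forward
// sensitivities. Dense linear algebra via Armadillo.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Forward rollout of tau dx/dt = -x + W(phi(x) - phi(x_sp)) + x_sp + h(t)
// from X0 (N x k), with phi = beta-blended rectifier (beta = 1: relu).
static cube rollout_cube(const mat& W, const vec& x_sp, const mat& X0,
                         const vec& h_vals, double dt, double tau,
                         bool linear) {
  const uword N = W.n_rows, k = X0.n_cols, nt = h_vals.n_elem;
  cube traj(N, k, nt);
  vec r_sp = linear ? x_sp : clamp(x_sp, 0.0, datum::inf);
  mat X = X0;
  for (uword i = 0; i < nt; ++i) {
    traj.slice(i) = X;
    if (i + 1 == nt) break;
    mat R = linear ? X : clamp(X, 0.0, datum::inf);
    R.each_col() -= r_sp;
    mat upd = -X + W * R;
    upd.each_col() += x_sp + h_vals(i);
    X += (dt / tau) * upd;
  }
  return traj;
}

// [[Rcpp::export]]
Rcpp::List calib_core_cpp(const arma::mat& W, const arma::vec& x_sp,
                          const arma::mat& C, const arma::mat& X0,
                          const arma::cube& m_star, const arma::vec& h_vals,
                          double dt, double tau, double dts, bool linear,
                          bool with_grad, bool with_gw) {
  const uword N = W.n_rows, k = X0.n_cols, nt = h_vals.n_elem;
  cube traj = rollout_cube(W, x_sp, X0, h_vals, dt, tau, linear);
  // loss
  double loss = 0.0;
  cube E(2, k, nt);
  for (uword i = 0; i < nt; ++i) {
    mat R = linear ? traj.slice(i)
                   : clamp(traj.slice(i), 0.0, datum::inf);
    mat e = C * R - m_star.slice(i);
    E.slice(i) = e;
    loss += accu(square(e)) * dts;
  }
  loss /= k;
  if (!with_grad) {
    return Rcpp::List::create(Rcpp::Named("loss") = loss);
  }
  mat gC(2, N, fill::zeros);
  mat lam(N, k, fill::zeros);
  mat gW;
  if (with_gw) gW.zeros(N, N);
  mat Wt = W.t();
  vec r_sp = linear ? x_sp : clamp(x_sp, 0.0, datum::inf);
  for (uword ii = nt; ii-- > 0;) {
    mat Xi = traj.slice(ii);
    mat Ri = linear ? Xi : clamp(Xi, 0.0, datum::inf);
    mat Dp = linear ? mat(N, k, fill::ones)
                    : conv_to<mat>::from(Xi > 0.0);
    gC += (2.0 * dts / k) * E.slice(ii) * Ri.t();
    lam += (2.0 * dts / k) * (Dp % (C.t() * E.slice(ii)));
    if (ii == 0) break;
    mat Xp = traj.slice(ii - 1);
    mat Dpp = linear ? mat(N, k, fill::ones)
                     : conv_to<mat>::from(Xp > 0.0);
    if (with_gw) {
      mat Rp = linear ? Xp : clamp(Xp, 0.0, datum::inf);
      Rp.each_col() -= r_sp;
      gW += (dt / tau) * (lam * Rp.t());
    }
    lam += (dt / tau) * (-lam + Dpp % (Wt * lam));
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loss") = loss, Rcpp::Named("gC") = gC,
      Rcpp::Named("gXs") = lam);
  if (with_gw) out["gW"] = gW;
  return out;
}

// [[Rcpp::export]]
Rcpp::List gn_condition_cpp(const arma::mat& W, const arma::vec& x_sp,
                            const arma::mat& C, const arma::vec& x0,
                            const arma::mat& m_star_j,
                            const arma::vec& h_vals, double dt, double tau,
                            double w) {
  // Gauss-Newton blocks for one condition: JtJ = sum_t w J_t' J_t and
  // Jtr = sum_t w J_t' r_t with J_t = C diag(phi'(x_t)) S_t, where S_t is
  // the sensitivity of x_t to the initial condition.
  const uword N = W.n_rows, nt = h_vals.n_elem;
  vec r_sp = clamp(x_sp, 0.0, datum::inf);
  vec x = x0;
  mat S(N, N, fill::eye);
  mat JtJ(N, N, fill::zeros);
  vec Jtr(N, fill::zeros);
  for (uword i = 0; i < nt; ++i) {
    vec r = clamp(x, 0.0, datum::inf);
    vec dphi = conv_to<vec>::from(x > 0.0);
    mat Cd = C;
    Cd.each_row() %= dphi.t();
    mat Jx = Cd * S;                            // 2 x N
    vec res = C * r - m_star_j.col(i);
    JtJ += w * (Jx.t() * Jx);
    Jtr += w * (Jx.t() * res);
    if (i + 1 == nt) break;
    mat Sd = S;
    Sd.each_col() %= dphi;
    S += (dt / tau) * (-S + W * Sd);
    x += (dt / tau) * (-x + W * (r - r_sp) + x_sp + h_vals(i));
  }
  return Rcpp::List::create(Rcpp::Named("JtJ") = JtJ,
                            Rcpp::Named("Jtr") = Jtr);
}

// [[Rcpp::export]]
Rcpp::List loop_sim_cpp(const arma::mat& W, const arma::vec& h_bar,
                        const arma::mat& Kfb, const arma::mat& Kyx,
                        const arma::mat& u_star, const arma::mat& X0,
                        const arma::vec& h_move, const arma::mat& pert,
                        int p_on, int p_off, double tau, double tau_y,
                        double tau_z, double dt, int n_pre, int n_prep,
                        int nt) {
  // Gated thalamo-cortical loop (design-z formulation): cortex x (N x k),
  // thalamus y (NE x k, silenced while the gate is closed), unit-coupled
  // layer-4 integrator z whose drive on cortex is Kfb = Kxz Kzy. h_move(i)
  // is the condition-independent bump at step i; pert (N x k) is an
  // additive input active for steps in [p_on, p_off).
  const uword N = W.n_rows, k = X0.n_cols, NE = Kyx.n_rows;
  cube xs(N, k, nt), ys(NE, k, nt), zs(NE, k, nt);
  mat X = X0;
  mat Y(NE, k, fill::zeros), Z(NE, k, fill::zeros);
  for (int i = 0; i < nt; ++i) {
    xs.slice(i) = X; ys.slice(i) = Y; zs.slice(i) = Z;
    if (i + 1 == nt) break;
    bool gate_on = (i >= n_pre) && (i < n_pre + n_prep);
    mat R = clamp(X, 0.0, datum::inf);
    mat drive = W * R - X + Kfb * clamp(Z, 0.0, datum::inf);
    drive.each_col() += h_bar;
    if (gate_on) drive += u_star;
    if (h_move(i) != 0.0) drive += h_move(i);
    if (i >= p_on && i < p_off) drive += pert;
    X += (dt / tau) * drive;
    if (gate_on) {
      Y += (dt / tau_y) * (-Y + Kyx * clamp(X, 0.0, datum::inf));
    } else {
      Y.zeros();
    }
    Z += (dt / tau_z) * (-Z + clamp(Y, 0.0, datum::inf));
  }
  return Rcpp::List::create(Rcpp::Named("x") = xs, Rcpp::Named("y") = ys,
                            Rcpp::Named("z") = zs);
}

// [[Rcpp::export]]
Rcpp::List refit_core_cpp(const arma::mat& W, const arma::vec& x_sp,
                          const arma::mat& C, const arma::mat& Xs,
                          const arma::cube& m_star, const arma::vec& h_vals,
                          const arma::mat& Kxz, const arma::mat& Kzyx,
                          const arma::vec& decay, double dt, double tau,
                          double dts, bool with_grad) {
  // Movement rollout with the decaying layer-4 transient: z0 = Kzyx phi(x*)
  // decays by the discrete factor `decay` and drives cortex through Kxz.
  const uword N = W.n_rows, k = Xs.n_cols, nt = h_vals.n_elem;
  vec r_sp = clamp(x_sp, 0.0, datum::inf);
  mat Z0 = Kzyx * clamp(Xs, 0.0, datum::inf);
  cube traj(N, k, nt);
  mat X = Xs;
  for (uword i = 0; i < nt; ++i) {
    traj.slice(i) = X;
    if (i + 1 == nt) break;
    mat R = clamp(X, 0.0, datum::inf);
    R.each_col() -= r_sp;
    mat upd = -X + W * R + Kxz * (Z0 * decay(i));
    upd.each_col() += x_sp + h_vals(i);
    X += (dt / tau) * upd;
  }
  double loss = 0.0;
  cube E(C.n_rows, k, nt);
  for (uword i = 0; i < nt; ++i) {
    mat e = C * clamp(traj.slice(i), 0.0, datum::inf) - m_star.slice(i);
    E.slice(i) = e;
    loss += accu(square(e)) * dts;
  }
  loss /= k;
  if (!with_grad) return Rcpp::List::create(Rcpp::Named("loss") = loss);
  mat lam(N, k, fill::zeros);
  mat gZ0(Z0.n_rows, k, fill::zeros);
  mat Wt = W.t();
  mat Kxzt = Kxz.t();
  for (uword ii = nt; ii-- > 0;) {
    mat Xi = traj.slice(ii);
    mat Dp = conv_to<mat>::from(Xi > 0.0);
    lam += (2.0 * dts / k) * (Dp % (C.t() * E.slice(ii)));
    if (ii == 0) break;
    mat Xp = traj.slice(ii - 1);
    gZ0 += (dt / tau) * decay(ii - 1) * (Kxzt * lam);
    lam += (dt / tau) * (-lam + conv_to<mat>::from(Xp > 0.0) % (Wt * lam));
  }
  mat gXs = lam + conv_to<mat>::from(Xs > 0.0) % (Kzyx.t() * gZ0);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("gXs") = gXs);
}
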