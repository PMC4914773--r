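// Numerical engines: adaptive RK45 for the macroscopic rate equations and the
// LNA moment system, exact SSA for intrinsic noise, batched population solves,
// and the O(N^2) Gaussian-KDE mutual-information evaluator.
//
// All reactions are elementary mass action with at most two (distinct)
// reactant species; the zeroth-order MEK-activation reaction carries the
// time-dependent input u(t) instead of a constant rate.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct MassActionModel {
  arma::mat S;                 // species x reactions stoichiometry
  std::vector<std::vector<int>> reactants; // per-reaction reactant indices
  arma::vec rates;             // per-reaction rate constants (input slot unused)
  int input_rxn;               // 0-based index of the zeroth-order input, -1 if none
  int input_form;              // 0 = step, 1 = smooth exponential decay
  double k1, k10, Tp;
  int n_species() const { return (int)S.n_rows; }
  int n_rxn() const { return (int)S.n_cols; }

  double input_rate(double t) const {
    if (input_form == 0) return (t < Tp) ? k1 : k10;
    return k10 + (k1 - k10) * std::exp(-t / Tp);
  }

  // concentration-scale propensities
  void propensities(double t, const arma::vec& x, arma::vec& f) const {
    for (int j = 0; j < n_rxn(); ++j) {
      if (j == input_rxn) { f(j) = input_rate(t); continue; }
      double p = rates(j);
      for (int r : reactants[j]) p *= x(r);
      f(j) = p;
    }
  }

  void drift(double t, const arma::vec& x, arma::vec& dx, arma::vec& f) const {
    propensities(t, x, f);
    dx = S * f;
  }

  // Jacobian of S*f(x); mass-action orders are 0/1 so derivatives are products
  // of the remaining reactant concentrations.
  void jacobian(const arma::vec& x, arma::mat& J) const {
    J.zeros(n_species(), n_species());
    for (int j = 0; j < n_rxn(); ++j) {
      if (j == input_rxn) continue; // zeroth order: no state dependence
      const std::vector<int>& rs = reactants[j];
      for (size_t a = 0; a < rs.size(); ++a) {
        double d = rates(j);
        for (size_t b = 0; b < rs.size(); ++b)
          if (b != a) d *= x(rs[b]);
        J.col(rs[a]) += d * S.col(j);
      }
    }
  }
};

MassActionModel make_model(const arma::mat& S, const List& reactant_list,
                           const arma::vec& rates, int input_rxn, int input_form,
                           double k1, double k10, double Tp) {
  MassActionModel m;
  m.S = S;
  m.rates = rates;
  m.input_rxn = input_rxn;
  m.input_form = input_form;
  m.k1 = k1; m.k10 = k10; m.Tp = Tp;
  m.reactants.resize(S.n_cols);
  for (int j = 0; j < (int)S.n_cols; ++j) {
    IntegerVector r = reactant_list[j];
    for (int i = 0; i < r.size(); ++i) m.reactants[j].push_back(r[i] - 1);
  }
  return m;
}

// ---- Dormand-Prince RK45 --------------------------------------------------

struct RhsBase {
  virtual void operator()(double t, const arma::vec& y, arma::vec& dy) const = 0;
  virtual ~RhsBase() {}
};

struct OdeRhs : RhsBase {
  const MassActionModel* m;
  mutable arma::vec f;
  explicit OdeRhs(const MassActionModel* mm) : m(mm), f(mm->n_rxn()) {}
  void operator()(double t, const arma::vec& y, arma::vec& dy) const override {
    m->drift(t, y, dy, f);
  }
};

// LNA state: [x (n); vec(Sigma) (n*n)], Sigma on the concentration scale.
struct LnaRhs : RhsBase {
  const MassActionModel* m;
  double omega;
  mutable arma::vec f;
  mutable arma::mat J, Sig, dSig;
  LnaRhs(const MassActionModel* mm, double om)
    : m(mm), omega(om), f(mm->n_rxn()),
      J(mm->n_species(), mm->n_species()),
      Sig(mm->n_species(), mm->n_species()),
      dSig(mm->n_species(), mm->n_species()) {}
  void operator()(double t, const arma::vec& y, arma::vec& dy) const override {
    int n = m->n_species();
    arma::vec x = y.subvec(0, n - 1);
    arma::vec dx(n);
    m->drift(t, x, dx, f);
    m->jacobian(x, J);
    Sig = arma::reshape(y.subvec(n, n + n * n - 1), n, n);
    dSig = J * Sig + Sig * J.t() + (m->S * arma::diagmat(f) * m->S.t()) / omega;
    dy.set_size(n + n * n);
    dy.subvec(0, n - 1) = dx;
    dy.subvec(n, n + n * n - 1) = arma::vectorise(dSig);
  }
};

// Integrate rhs from t0 to t1, overwriting y. `h` and `k1v` (the FSAL
// derivative at y) persist across calls so the step size survives output
// stops. Returns false on failure.
bool rk45_segment(const RhsBase& rhs, arma::vec& y, double t0, double t1,
                  double rtol, double atol, long max_steps, long& steps_used,
                  double& h, arma::vec& k1v, bool& have_k1) {
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                      e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

  if (t1 <= t0) return true;
  const int n = (int)y.n_elem;
  arma::vec k2v(n), k3v(n), k4v(n), k5v(n), k6v(n), k7v(n), ytmp(n), ynew(n), err(n);
  double t = t0;
  if (h <= 0) h = std::min(0.1 * (t1 - t0), 1.0);
  if (!have_k1 || (int)k1v.n_elem != n) {
    k1v.set_size(n);
    rhs(t, y, k1v);
    have_k1 = true;
  }
  while (t < t1) {
    double h_try = std::min(h, t1 - t);
    if (++steps_used > max_steps) return false;
    ytmp = y + h_try * a21 * k1v;                            rhs(t + c2 * h_try, ytmp, k2v);
    ytmp = y + h_try * (a31 * k1v + a32 * k2v);              rhs(t + c3 * h_try, ytmp, k3v);
    ytmp = y + h_try * (a41 * k1v + a42 * k2v + a43 * k3v);  rhs(t + c4 * h_try, ytmp, k4v);
    ytmp = y + h_try * (a51 * k1v + a52 * k2v + a53 * k3v + a54 * k4v);
    rhs(t + c5 * h_try, ytmp, k5v);
    ytmp = y + h_try * (a61 * k1v + a62 * k2v + a63 * k3v + a64 * k4v + a65 * k5v);
    rhs(t + h_try, ytmp, k6v);
    ynew = y + h_try * (b1 * k1v + b3 * k3v + b4 * k4v + b5 * k5v + b6 * k6v);
    rhs(t + h_try, ynew, k7v);
    err = h_try * (e1 * k1v + e3 * k3v + e4 * k4v + e5 * k5v + e6 * k6v + e7 * k7v);
    double errnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      double sc = atol + rtol * std::max(std::abs(y(i)), std::abs(ynew(i)));
      double r = err(i) / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / n);
    if (!std::isfinite(errnorm)) return false;
    if (errnorm <= 1.0) {
      t += h_try;
      y = ynew;
      k1v = k7v; // FSAL
    }
    double fac = (errnorm > 0) ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
    h = h_try * std::min(5.0, std::max(0.2, fac));
    if (h < 1e-12) return false;
  }
  return true;
}

// Integrate through the output grid, splitting at the input discontinuity.
bool rk45_grid(const RhsBase& rhs, arma::vec y, const arma::vec& times,
               double Tp, bool split_at_Tp, double rtol, double atol,
               long max_steps, arma::mat& out) {
  out.set_size(times.n_elem, y.n_elem);
  long steps_used = 0;
  double t = times(0);
  double h = -1.0;
  arma::vec k1v;
  bool have_k1 = false;
  out.row(0) = y.t();
  for (size_t k = 1; k < times.n_elem; ++k) {
    double tk = times(k);
    if (split_at_Tp && t < Tp && tk > Tp) {
      if (!rk45_segment(rhs, y, t, Tp, rtol, atol, max_steps, steps_used,
                        h, k1v, have_k1)) return false;
      t = Tp;
      have_k1 = false; // drift is discontinuous at the pulse end
    }
    if (!rk45_segment(rhs, y, t, tk, rtol, atol, max_steps, steps_used,
                      h, k1v, have_k1)) return false;
    t = tk;
    out.row(k) = y.t();
  }
  return true;
}

} // namespace

// [[Rcpp::export]]
List cpp_solve_ode(const arma::mat& stoich, const List& reactants,
                   const arma::vec& rates, int input_rxn, int input_form,
                   double k1, double k10, double Tp,
                   const arma::vec& x0, const arma::vec& times,
                   double rtol, double atol, long max_steps = 200000) {
  MassActionModel m = make_model(stoich, reactants, rates, input_rxn - 1,
                                 input_form, k1, k10, Tp);
  OdeRhs rhs(&m);
  arma::mat out;
  bool ok = rk45_grid(rhs, x0, times, Tp, input_form == 0, rtol, atol, max_steps, out);
  return List::create(_["states"] = out, _["ok"] = ok);
}

// Batched deterministic solve over a population of cells: each row of
// `rate_mat` (cells x reactions), `k1v/k10v/Tpv`, and `x0_mat` describes one
// cell; returns observable trajectories obs = W * x(t).
// [[Rcpp::export]]
List cpp_solve_obs_many(const arma::mat& stoich, const List& reactants,
                        const arma::mat& rate_mat, int input_rxn, int input_form,
                        const arma::vec& k1v, const arma::vec& k10v, const arma::vec& Tpv,
                        const arma::mat& x0_mat, const arma::vec& times,
                        const arma::mat& W, double rtol, double atol,
                        long max_steps = 200000) {
  int ncell = (int)rate_mat.n_rows, ntime = (int)times.n_elem, nobs = (int)W.n_rows;
  arma::cube obs(ncell, ntime, nobs);
  arma::ivec ok(ncell, arma::fill::ones);
  MassActionModel m = make_model(stoich, reactants, rate_mat.row(0).t(),
                                 input_rxn - 1, input_form, k1v(0), k10v(0), Tpv(0));
  for (int c = 0; c < ncell; ++c) {
    m.rates = rate_mat.row(c).t();
    m.k1 = k1v(c); m.k10 = k10v(c); m.Tp = Tpv(c);
    OdeRhs rhs(&m);
    arma::mat out;
    if (!rk45_grid(rhs, x0_mat.row(c).t(), times, m.Tp, input_form == 0,
                   rtol, atol, max_steps, out)) {
      ok(c) = 0;
      obs.row(c).fill(NA_REAL);
      continue;
    }
    arma::mat o = out * W.t(); // ntime x nobs
    for (int k = 0; k < nobs; ++k) obs.slice(k).row(c) = o.col(k).t();
  }
  return List::create(_["obs"] = obs, _["ok"] = ok);
}

// LNA moments: returns species means (ntime x n) and covariances
// (n x n x ntime) on the concentration scale; Var ~ 1/omega.
// [[Rcpp::export]]
List cpp_lna(const arma::mat& stoich, const List& reactants,
             const arma::vec& rates, int input_rxn, int input_form,
             double k1, double k10, double Tp, double omega,
             const arma::vec& x0, const arma::vec& times,
             double rtol, double atol, long max_steps = 400000) {
  MassActionModel m = make_model(stoich, reactants, rates, input_rxn - 1,
                                 input_form, k1, k10, Tp);
  int n = m.n_species();
  LnaRhs rhs(&m, omega);
  arma::vec y(n + n * n, arma::fill::zeros);
  y.subvec(0, n - 1) = x0;
  arma::mat out;
  bool ok = rk45_grid(rhs, y, times, Tp, input_form == 0, rtol, atol, max_steps, out);
  arma::mat mean(times.n_elem, n);
  arma::cube cov(n, n, times.n_elem);
  if (ok) {
    for (size_t k = 0; k < times.n_elem; ++k) {
      mean.row(k) = out(k, arma::span(0, n - 1));
      arma::mat Sig = arma::reshape(out.row(k).subvec(n, n + n * n - 1).t(), n, n);
      cov.slice(k) = 0.5 * (Sig + Sig.t()); // enforce symmetry
    }
  }
  return List::create(_["mean"] = mean, _["cov"] = cov, _["ok"] = ok);
}

// ---- Gillespie SSA --------------------------------------------------------

namespace {

// count-scale propensities: zeroth order omega*u(t), unimolecular k*n,
// bimolecular (distinct species) k/omega * n1 * n2
double ssa_propensities(const MassActionModel& m, double t, double omega,
                        const arma::vec& n, arma::vec& a) {
  double a0 = 0.0;
  for (int j = 0; j < m.n_rxn(); ++j) {
    double p;
    if (j == m.input_rxn) {
      p = omega * m.input_rate(t);
    } else {
      p = m.rates(j);
      const std::vector<int>& rs = m.reactants[j];
      for (int r : rs) p *= n(r);
      if (rs.size() == 2) p /= omega;
    }
    a(j) = p;
    a0 += p;
  }
  return a0;
}

// One exact SSA path recorded at `times`. Uses R's RNG (caller sets the seed).
// For the step input the pulse end is an exact event boundary; for the smooth
// input the zeroth-order channel is simulated by thinning against the bound
// max(u(t), k10) (u is monotone toward k10).
void ssa_run(const MassActionModel& m, double omega, arma::vec n,
             const arma::vec& times, arma::mat& out) {
  int ns = m.n_species(), nr = m.n_rxn();
  arma::vec a(nr);
  double t = times(0);
  size_t next_out = 0;
  out.set_size(times.n_elem, ns);
  while (next_out < times.n_elem && times(next_out) <= t) {
    out.row(next_out++) = n.t();
  }
  const double t_end = times(times.n_elem - 1);
  bool thinning = (m.input_form != 0) && (m.input_rxn >= 0);
  while (t < t_end) {
    double bound = 1.0;
    double a0 = ssa_propensities(m, t, omega, n, a);
    if (thinning) {
      bound = std::max(m.input_rate(t), m.k10);
      a0 += omega * bound - a(m.input_rxn);
      a(m.input_rxn) = omega * bound;
    }
    if (a0 <= 0.0) { t = t_end; }
    else {
      double tau = R::exp_rand() / a0;
      // step input: if the jump would cross the pulse boundary, restart there
      if (m.input_form == 0 && m.input_rxn >= 0 && t < m.Tp && t + tau > m.Tp) {
        t = m.Tp;
        while (next_out < times.n_elem && times(next_out) <= t) out.row(next_out++) = n.t();
        continue;
      }
      t += tau;
      while (next_out < times.n_elem && times(next_out) <= std::min(t, t_end))
        out.row(next_out++) = n.t();
      if (t >= t_end) break;
      double u = unif_rand() * a0, cum = 0.0;
      int j = nr - 1;
      for (int jj = 0; jj < nr; ++jj) { cum += a(jj); if (u <= cum) { j = jj; break; } }
      if (thinning && j == m.input_rxn) {
        // accept the input firing with probability u(t)/bound, else phantom
        if (unif_rand() > m.input_rate(t) / bound) continue;
      }
      n += m.S.col(j);
    }
  }
  while (next_out < times.n_elem) out.row(next_out++) = n.t();
}

} // namespace

// [[Rcpp::export]]
arma::mat cpp_ssa(const arma::mat& stoich, const List& reactants,
                  const arma::vec& rates, int input_rxn, int input_form,
                  double k1, double k10, double Tp, double omega,
                  const arma::vec& n0, const arma::vec& times) {
  MassActionModel m = make_model(stoich, reactants, rates, input_rxn - 1,
                                 input_form, k1, k10, Tp);
  RNGScope scope;
  arma::mat out;
  ssa_run(m, omega, n0, times, out);
  return out;
}

// n_rep independent SSA paths; returns observable counts W * n(t) as a cube
// (rep x time x observable).
// [[Rcpp::export]]
arma::cube cpp_ssa_obs_many(const arma::mat& stoich, const List& reactants,
                            const arma::vec& rates, int input_rxn, int input_form,
                            double k1, double k10, double Tp, double omega,
                            const arma::vec& n0, const arma::vec& times,
                            const arma::mat& W, int n_rep) {
  MassActionModel m = make_model(stoich, reactants, rates, input_rxn - 1,
                                 input_form, k1, k10, Tp);
  RNGScope scope;
  int ntime = (int)times.n_elem, nobs = (int)W.n_rows;
  arma::cube obs(n_rep, ntime, nobs);
  arma::mat out;
  for (int r = 0; r < n_rep; ++r) {
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
    ssa_run(m, omega, n0, times, out);
    arma::mat o = out * W.t();
    for (int k = 0; k < nobs; ++k) obs.slice(k).row(r) = o.col(k).t();
  }
  return obs;
}

// SSA paths where each replicate carries its own parameters/initial counts
// (population simulation with intrinsic noise on).
// [[Rcpp::export]]
arma::cube cpp_ssa_obs_population(const arma::mat& stoich, const List& reactants,
                                  const arma::mat& rate_mat, int input_rxn, int input_form,
                                  const arma::vec& k1v, const arma::vec& k10v,
                                  const arma::vec& Tpv, double omega,
                                  const arma::mat& n0_mat, const arma::vec& times,
                                  const arma::mat& W) {
  MassActionModel m = make_model(stoich, reactants, rate_mat.row(0).t(),
                                 input_rxn - 1, input_form, k1v(0), k10v(0), Tpv(0));
  RNGScope scope;
  int ncell = (int)rate_mat.n_rows, ntime = (int)times.n_elem, nobs = (int)W.n_rows;
  arma::cube obs(ncell, ntime, nobs);
  arma::mat out;
  for (int c = 0; c < ncell; ++c) {
    if (c % 64 == 0) Rcpp::checkUserInterrupt();
    m.rates = rate_mat.row(c).t();
    m.k1 = k1v(c); m.k10 = k10v(c); m.Tp = Tpv(c);
    ssa_run(m, omega, n0_mat.row(c).t(), times, out);
    arma::mat o = out * W.t();
    for (int k = 0; k < nobs; ++k) obs.slice(k).row(c) = o.col(k).t();
  }
  return obs;
}

// ---- KDE mutual information ----------------------------------------------

// Plug-in MI estimate (nats) with product Gaussian kernels evaluated at the
// sample points; hx, hy are the marginal kernel SDs.
// [[Rcpp::export]]
double cpp_mi_kde(const arma::vec& x, const arma::vec& y, double hx, double hy) {
  const int n = (int)x.n_elem;
  const double cx = 1.0 / (hx * std::sqrt(2.0 * M_PI));
  const double cy = 1.0 / (hy * std::sqrt(2.0 * M_PI));
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
    double fx = 0.0, fy = 0.0, fxy = 0.0;
    for (int j = 0; j < n; ++j) {
      double zx = (x(i) - x(j)) / hx, zy = (y(i) - y(j)) / hy;
      double kx = std::exp(-0.5 * zx * zx), ky = std::exp(-0.5 * zy * zy);
      fx += kx; fy += ky; fxy += kx * ky;
    }
    fx *= cx / n; fy *= cy / n; fxy *= cx * cy / n;
    acc += std::log(fxy / (fx * fy));
  }
  return acc / n;
}
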