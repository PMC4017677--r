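// Bounded-variable primal simplex (revised form, dense) for small LPs
//
//   minimise  c'x   subject to  A x = b,  lb <= x <= ub
//
// Two phases with artificial variables; nonbasic variables sit at one of
// their bounds; the basis inverse is maintained explicitly with rank-1
// (product-form) updates and periodic refactorisation.  Dantzig pricing
// with a Bland fallback against cycling; deterministic tie-breaking so
// identical programs always return the same vertex.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double DUAL_TOL = 1e-9;   // reduced-cost optimality tolerance
static const double PIV_TOL = 1e-11;   // ratio-test eligibility threshold
// (the Harris-style second pass picks the largest pivot among near-ties,
// so eligibility can be generous without admitting bad pivots)
static const double FEAS_TOL = 1e-7;   // phase-1 residual considered zero
static const double BOUND_INF = 1e14;  // bounds beyond this act as infinite

namespace {

struct Simplex {
  uword m, n, ntot;           // rows, structural cols, cols incl. artificials
  mat A;                      // m x ntot
  vec b, lo, hi, cost;
  uvec basis;                 // m basic column indices
  std::vector<int> state;     // nonbasic: 0 at lower, 1 at upper; 2 basic
  mat Binv;
  vec xB;                     // values of basic variables
  uword stall = 0;
  uword iters = 0, max_iters = 0;
  uword refactor_every = 10;

  bool refactor() {
    mat B(m, m);
    for (uword i = 0; i < m; ++i) B.col(i) = A.col(basis(i));
    mat Bi;
    if (!inv(Bi, B)) return false;
    Binv = Bi;
    recompute_xB();
    return true;
  }

  void recompute_xB() {
    vec rhs = b;
    for (uword j = 0; j < ntot; ++j) {
      if (state[j] == 2) continue;
      double v = (state[j] == 0) ? lo(j) : hi(j);
      if (v != 0.0) rhs -= v * A.col(j);
    }
    xB = Binv * rhs;
  }

  double nonbasic_value(uword j) const {
    return (state[j] == 0) ? lo(j) : hi(j);
  }

  // one simplex phase over the current cost vector; returns
  // 0 optimal, 2 unbounded, 3 iteration limit
  int iterate(const std::vector<bool>& allowed) {
    while (iters++ < max_iters) {
      // pricing: y' = c_B' Binv, d_j = c_j - y' A_j
      vec y(m);
      {
        vec cB(m);
        for (uword i = 0; i < m; ++i) cB(i) = cost(basis(i));
        y = Binv.t() * cB;
      }
      sword enter = -1;
      int enter_dir = 0;             // +1 increase (at lower), -1 decrease
      double best = DUAL_TOL;
      bool bland = stall > 60;
      for (uword j = 0; j < ntot; ++j) {
        if (state[j] == 2 || !allowed[j]) continue;
        if (lo(j) == hi(j)) continue;            // fixed variable
        double d = cost(j) - dot(y, A.col(j));
        double viol = (state[j] == 0) ? -d : d;  // improvement rate
        if (viol > (bland ? DUAL_TOL : best)) {
          enter = (sword)j;
          enter_dir = (state[j] == 0) ? 1 : -1;
          if (bland) break;
          best = viol;
        }
      }
      if (enter < 0) return 0;

      vec w = Binv * A.col((uword)enter);        // direction in basics
      // entering variable moves by t >= 0 (times enter_dir);
      // basic i changes by -enter_dir * w(i) * t
      //
      // Harris two-pass ratio test: pass 1 computes the minimal *relaxed*
      // ratio (room widened by tol_feas), pass 2 picks, among rows whose
      // strict ratio fits under it, the numerically best pivot.  Any
      // basic then leaves its bounds by at most tol_feas per step.
      // under Bland fallback the relaxation must vanish: Bland's
      // anti-cycling guarantee needs the strict minimal ratio
      const double tol_feas = bland ? 0.0 : 1e-9;
      const double elig = 1e-13;
      double t_flip = hi((uword)enter) - lo((uword)enter);

      double t_rel_min = t_flip;
      for (uword i = 0; i < m; ++i) {
        double delta = -enter_dir * w(i);
        double ad = std::fabs(delta);
        if (ad <= elig) continue;
        double room;
        if (delta < 0) room = xB(i) - lo(basis(i));
        else {
          if (hi(basis(i)) >= BOUND_INF) continue;
          room = hi(basis(i)) - xB(i);
        }
        if (room < 0) room = 0;
        double t_rel = (room + tol_feas) / ad;
        if (t_rel < t_rel_min) t_rel_min = t_rel;
      }
      if (t_rel_min >= BOUND_INF) return 2;      // unbounded (no box limit)

      sword leave = -1;                          // -1 => bound flip
      int leave_to = 0;                          // 0 lower, 1 upper
      double best_piv = 0.0, t_max = t_flip;
      for (uword i = 0; i < m; ++i) {
        double delta = -enter_dir * w(i);
        double ad = std::fabs(delta);
        if (ad <= elig) continue;
        double room; int to;
        if (delta < 0) { room = xB(i) - lo(basis(i)); to = 0; }
        else {
          if (hi(basis(i)) >= BOUND_INF) continue;
          room = hi(basis(i)) - xB(i); to = 1;
        }
        if (room < 0) room = 0;
        double t_strict = room / ad;
        if (t_strict > t_rel_min) continue;
        bool better;
        if (bland) {
          better = (leave < 0) || basis(i) < basis((uword)leave);
        } else {
          better = (leave < 0) || ad > best_piv * (1.0 + 1e-12) ||
                   (ad > best_piv * (1.0 - 1e-12) &&
                    basis(i) < basis((uword)leave));
        }
        if (better) {
          leave = (sword)i; leave_to = to; best_piv = ad; t_max = t_strict;
        }
      }
      if (leave < 0) t_max = t_flip;             // nothing blocks: flip
      if (t_max > t_flip) { t_max = t_flip; leave = -1; }
      if (t_max < 1e-10) ++stall; else stall = 0;

      // apply step
      for (uword i = 0; i < m; ++i) xB(i) -= enter_dir * w(i) * t_max;
      if (leave < 0) {                           // bound flip, basis unchanged
        state[(uword)enter] = (state[(uword)enter] == 0) ? 1 : 0;
        continue;
      }
      uword li = (uword)leave;
      uword lj = basis(li);
      double enter_val = nonbasic_value((uword)enter) + enter_dir * t_max;

      // pivot: update Binv by rank-1 elimination on row li
      double piv = w(li);
      if (std::fabs(piv) < PIV_TOL) { if (!refactor()) return 4; continue; }
      rowvec br = Binv.row(li) / piv;
      for (uword i = 0; i < m; ++i) {
        if (i == li) continue;
        double f = w(i);
        if (f != 0.0) Binv.row(i) -= f * br;
      }
      Binv.row(li) = br;

      state[lj] = leave_to;                      // leaving var to its bound
      state[(uword)enter] = 2;
      basis(li) = (uword)enter;
      xB(li) = enter_val;

      if (iters % refactor_every == 0 && !refactor()) return 4;
    }
    return 3;
  }
};

} // namespace

// geometric-mean equilibration; scales rounded to powers of two
static void equilibrate(const mat& A, vec& rscale, vec& cscale) {
  const uword m = A.n_rows, n = A.n_cols;
  rscale.ones(m); cscale.ones(n);
  mat W = abs(A);
  for (int pass = 0; pass < 3; ++pass) {
    for (uword i = 0; i < m; ++i) {
      double hi = 0, lo = datum::inf;
      for (uword j = 0; j < n; ++j) {
        double v = W(i, j) * rscale(i) * cscale(j);
        if (v > 0) { hi = std::max(hi, v); lo = std::min(lo, v); }
      }
      if (hi > 0) {
        double sfac = 1.0 / std::sqrt(hi * lo);
        rscale(i) *= std::exp2(std::round(std::log2(sfac)));
      }
    }
    for (uword j = 0; j < n; ++j) {
      double hi = 0, lo = datum::inf;
      for (uword i = 0; i < m; ++i) {
        double v = W(i, j) * rscale(i) * cscale(j);
        if (v > 0) { hi = std::max(hi, v); lo = std::min(lo, v); }
      }
      if (hi > 0) {
        double sfac = 1.0 / std::sqrt(hi * lo);
        cscale(j) *= std::exp2(std::round(std::log2(sfac)));
      }
    }
  }
}

// single attempt at solving; refactor_every controls numerical paranoia
static Rcpp::List lp_attempt(const arma::vec& cvec0, const arma::mat& A0,
                             const arma::vec& bvec0, const arma::vec& lb0,
                             const arma::vec& ub0, arma::uword refactor_every) {
  const uword n = cvec0.n_elem;
  const uword m = A0.n_rows;

  // scaled problem: x0 = Dc x, rows premultiplied by Dr
  vec rs, cs;
  equilibrate(A0, rs, cs);
  mat A = A0;
  for (uword i = 0; i < m; ++i)
    for (uword j = 0; j < n; ++j)
      A(i, j) *= rs(i) * cs(j);
  vec bvec = bvec0 % rs;
  vec lb = lb0 / cs, ub = ub0 / cs;
  vec cvec = cvec0 % cs;

  Simplex S;
  S.m = m; S.n = n; S.ntot = n + m;
  S.refactor_every = refactor_every;
  S.A.set_size(m, S.ntot);
  S.A.cols(0, n - 1) = A;
  S.b = bvec;
  S.lo.set_size(S.ntot); S.hi.set_size(S.ntot);
  S.lo.subvec(0, n - 1) = lb;
  S.hi.subvec(0, n - 1) = ub;
  S.state.assign(S.ntot, 0);
  S.basis.set_size(m);
  S.max_iters = 2000 + 200 * (m + n);

  // start: structurals at the bound of smaller magnitude (finite)
  for (uword j = 0; j < n; ++j) {
    bool lo_fin = lb(j) > -BOUND_INF, hi_fin = ub(j) < BOUND_INF;
    if (lo_fin && (!hi_fin || std::fabs(lb(j)) <= std::fabs(ub(j))))
      S.state[j] = 0;
    else if (hi_fin) S.state[j] = 1;
    else S.state[j] = 0;
  }

  // residual determines artificial signs
  vec resid = bvec;
  for (uword j = 0; j < n; ++j) {
    double v = (S.state[j] == 0) ? lb(j) : ub(j);
    if (!std::isfinite(v)) v = 0.0;
    if (v != 0.0) resid -= v * A.col(j);
  }
  for (uword i = 0; i < m; ++i) {
    uword aj = n + i;
    S.A.col(aj).zeros();
    S.A(i, aj) = (resid(i) >= 0.0) ? 1.0 : -1.0;
    S.lo(aj) = 0.0;
    S.hi(aj) = datum::inf;
    S.state[aj] = 2;
    S.basis(i) = aj;
  }

  S.Binv.eye(m, m);
  for (uword i = 0; i < m; ++i)
    if (S.A(i, n + i) < 0) S.Binv(i, i) = -1.0;
  S.recompute_xB();

  std::vector<bool> allowed(S.ntot, true);

  // phase 1: minimise sum of artificials.  The relaxed (Harris-style)
  // ratio test lets variables drift slightly off their bounds, so after
  // convergence refactorise, recompute the true artificial sum, and
  // resume if genuine infeasibility remains unresolved.
  S.cost.zeros(S.ntot);
  for (uword j = n; j < S.ntot; ++j) S.cost(j) = 1.0;
  double p1 = datum::inf;
  for (int round = 0; round < 40; ++round) {
    int st1 = S.iterate(allowed);
    if (st1 == 3 || st1 == 4)
      return Rcpp::List::create(Rcpp::Named("status") = st1);
    if (!S.refactor())
      return Rcpp::List::create(Rcpp::Named("status") = 4);
    double p1_new = 0.0;
    for (uword i = 0; i < m; ++i)
      if (S.basis(i) >= n) p1_new += std::max(S.xB(i), 0.0);
    bool stalled = p1_new >= p1 * (1.0 - 1e-6);
    p1 = p1_new;
    if (p1 <= FEAS_TOL || stalled) break;
    S.stall = 61;          // continue under Bland: guaranteed progress
  }
  if (p1 > FEAS_TOL)
    return Rcpp::List::create(Rcpp::Named("status") = 1);

  // fix artificials at zero so they can never re-enter or move
  for (uword j = n; j < S.ntot; ++j) {
    allowed[j] = false;
    S.hi(j) = 0.0;
    if (S.state[j] != 2) S.state[j] = 0;
  }

  // phase 2 (same drift-cleanup loop as phase 1)
  S.cost.zeros(S.ntot);
  S.cost.subvec(0, n - 1) = cvec;
  S.stall = 0;
  for (int round = 0; round < 3; ++round) {
    int st2 = S.iterate(allowed);
    if (st2 != 0) return Rcpp::List::create(Rcpp::Named("status") = st2);
    if (!S.refactor())
      return Rcpp::List::create(Rcpp::Named("status") = 4);
  }

  vec x(n);
  for (uword j = 0; j < n; ++j)
    x(j) = (S.state[j] == 0) ? S.lo(j) :
           (S.state[j] == 1) ? S.hi(j) : 0.0;
  for (uword i = 0; i < m; ++i)
    if (S.basis(i) < n) x(S.basis(i)) = S.xB(i);
  x = x % cs;                      // back to original units
  double objval = dot(cvec0, x);

  return Rcpp::List::create(Rcpp::Named("status") = 0,
                            Rcpp::Named("x") = x,
                            Rcpp::Named("obj") = objval);
}

// status codes: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit,
// 4 numerically singular basis
// [[Rcpp::export(name = ".cpp_lp_dense")]]
Rcpp::List cpp_lp_dense(const arma::vec& cvec,
                        const arma::mat& A,
                        const arma::vec& bvec,
                        const arma::vec& lb,
                        const arma::vec& ub) {
  const uword n = cvec.n_elem;
  const uword m = A.n_rows;
  if (A.n_cols != n || bvec.n_elem != m || lb.n_elem != n || ub.n_elem != n)
    Rcpp::stop("lp: dimension mismatch");
  for (uword j = 0; j < n; ++j)
    if (lb(j) > ub(j) + 1e-12)
      Rcpp::stop("lp: lower bound exceeds upper bound");

  Rcpp::List res = lp_attempt(cvec, A, bvec, lb, ub, 10);
  int st = Rcpp::as<int>(res["status"]);
  if (st == 4)   // ill-conditioned: retry with a fresh factorisation per pivot
    res = lp_attempt(cvec, A, bvec, lb, ub, 1);
  return res;
}
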