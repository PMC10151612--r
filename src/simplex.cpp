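// Bounded-variable two-phase primal simplex for flux-balance problems.
//
// Solves   maximize  c'x   s.t.  rlb <= A x <= rub,  lb <= x <= ub
// with all variable and row bounds finite. Internally rows are turned into
// slack variables w (A x - w = 0, rlb <= w <= rub) so the working system is
// an equality system over z = (x, w) with box bounds, which is the natural
// shape of an FBA problem (S x = c', bounds on both). Phase 1 drives
// artificial columns to zero; phase 2 optimizes the user objective. Dantzig
// pricing with a Bland fallback guards against cycling on the heavily
// degenerate LPs that steady-state stoichiometries produce.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// nonbasic status
enum Status { AT_LOWER = 0, AT_UPPER = 1, BASIC = 2 };

struct Simplex {
  int m;                 // rows (constraints)
  int n;                 // structural + slack variables
  int ntot;              // n + m artificials
  std::vector<double> T; // m x ntot dense tableau, row-major
  std::vector<double> lo, hi, val; // per variable
  std::vector<int> basis;          // size m, variable index basic in row i
  std::vector<int> stat;           // per variable
  std::vector<double> beta;        // basic values, size m
  double eps_piv = 1e-9;
  double eps_d   = 1e-9;
  double eps_feas = 1e-7;

  inline double& t(int i, int j) { return T[(size_t)i * ntot + j]; }

  // recompute basic values from nonbasic bound values (b = 0 always)
  void refresh_beta() {
    std::fill(beta.begin(), beta.end(), 0.0);
    for (int j = 0; j < ntot; ++j) {
      if (stat[j] == BASIC) continue;
      double v = val[j];
      if (v == 0.0) continue;
      for (int i = 0; i < m; ++i) beta[i] -= t(i, j) * v;
    }
  }

  // one simplex phase; cost c over all ntot columns (maximization).
  // returns 0 ok (optimal), 2 iteration limit
  int iterate(const std::vector<double>& c, long maxit) {
    std::vector<double> cb(m), d(ntot);
    bool bland = false;
    long stall = 0;
    for (long it = 0; it < maxit; ++it) {
      for (int i = 0; i < m; ++i) cb[i] = c[basis[i]];
      // reduced costs d = c - T' cb
      for (int j = 0; j < ntot; ++j) d[j] = c[j];
      for (int i = 0; i < m; ++i) {
        double cbi = cb[i];
        if (cbi == 0.0) continue;
        const double* row = &T[(size_t)i * ntot];
        for (int j = 0; j < ntot; ++j) d[j] -= cbi * row[j];
      }
      // entering column
      int jin = -1, dir = 0;
      double best = eps_d;
      for (int j = 0; j < ntot; ++j) {
        if (stat[j] == BASIC) continue;
        if (lo[j] == hi[j]) continue; // fixed, cannot move
        if (stat[j] == AT_LOWER && d[j] > eps_d) {
          if (bland) { jin = j; dir = +1; break; }
          if (d[j] > best) { best = d[j]; jin = j; dir = +1; }
        } else if (stat[j] == AT_UPPER && d[j] < -eps_d) {
          if (bland) { jin = j; dir = -1; break; }
          if (-d[j] > best) { best = -d[j]; jin = j; dir = -1; }
        }
      }
      if (jin < 0) return 0; // optimal for this phase
      // ratio test: t >= 0 is movement of entering var in direction dir
      double tmax = hi[jin] - lo[jin]; // own bound flip
      int rout = -1;
      double pivbest = 0.0;
      for (int i = 0; i < m; ++i) {
        double rho = -dir * t(i, jin); // d(beta_i)/dt
        double lim;
        if (rho > eps_piv) {
          double ub = hi[basis[i]];
          if (ub >= INF) continue;
          lim = (ub - beta[i]) / rho;
        } else if (rho < -eps_piv) {
          double lb = lo[basis[i]];
          if (lb <= -INF) continue;
          lim = (lb - beta[i]) / rho;
        } else continue;
        if (lim < 0) lim = 0;
        bool take = false;
        if (rout < 0) {
          take = (lim <= tmax);
        } else if (lim < tmax - 1e-12) {
          take = true;
        } else if (lim <= tmax + 1e-12) { // tie-break: big pivot, or Bland
          take = bland ? (basis[i] < basis[rout])
                       : (std::fabs(t(i, jin)) > pivbest);
        }
        if (take) {
          rout = i; pivbest = std::fabs(t(i, jin));
          if (lim < tmax) tmax = lim;
        }
      }
      if (tmax >= INF) return 3; // unbounded (finite boxes make this rare)
      if (tmax < 1e-11) { if (++stall > 2 * (long)(m + n)) bland = true; }
      else stall = 0;
      // update basic values
      for (int i = 0; i < m; ++i) beta[i] += (-dir * t(i, jin)) * tmax;
      if (rout < 0) { // bound flip
        stat[jin] = (dir > 0) ? AT_UPPER : AT_LOWER;
        val[jin] = (dir > 0) ? hi[jin] : lo[jin];
        continue;
      }
      // pivot: basis[rout] leaves to the bound it hit, jin enters
      int jout = basis[rout];
      double rho = -dir * t(rout, jin);
      stat[jout] = (rho > 0) ? AT_UPPER : AT_LOWER;
      val[jout] = (rho > 0) ? hi[jout] : lo[jout];
      double enter_val = ((dir > 0) ? lo[jin] : hi[jin]) + dir * tmax;
      basis[rout] = jin;
      stat[jin] = BASIC;
      beta[rout] = enter_val;
      // eliminate column jin
      double piv = t(rout, jin);
      double* prow = &T[(size_t)rout * ntot];
      double ipiv = 1.0 / piv;
      for (int j = 0; j < ntot; ++j) prow[j] *= ipiv;
      for (int i = 0; i < m; ++i) {
        if (i == rout) continue;
        double f = t(i, jin);
        if (f == 0.0) continue;
        double* row = &T[(size_t)i * ntot];
        for (int j = 0; j < ntot; ++j) row[j] -= f * prow[j];
        row[jin] = 0.0; // exact
      }
      prow[jin] = 1.0;
      if ((it & 127) == 127) refresh_beta(); // curb drift
    }
    return 2;
  }
};

// [[Rcpp::export(name = ".simplex_solve")]]
List simplex_solve(NumericMatrix A, NumericVector row_lb, NumericVector row_ub,
                   NumericVector lb, NumericVector ub, NumericVector obj,
                   bool maximize) {
  int m = A.nrow(), nx = A.ncol();
  Simplex sp;
  sp.m = m;
  sp.n = nx + m;
  sp.ntot = sp.n + m;
  sp.T.assign((size_t)m * sp.ntot, 0.0);
  sp.lo.resize(sp.ntot); sp.hi.resize(sp.ntot); sp.val.resize(sp.ntot);
  sp.stat.assign(sp.ntot, AT_LOWER);
  sp.basis.resize(m);
  sp.beta.assign(m, 0.0);

  for (int j = 0; j < nx; ++j) {
    if (!std::isfinite(lb[j]) || !std::isfinite(ub[j]))
      stop("simplex backend requires finite variable bounds");
    if (lb[j] > ub[j]) stop("variable lower bound exceeds upper bound");
    sp.lo[j] = lb[j]; sp.hi[j] = ub[j];
    for (int i = 0; i < m; ++i) sp.t(i, j) = A(i, j);
  }
  for (int i = 0; i < m; ++i) {
    if (!std::isfinite(row_lb[i]) || !std::isfinite(row_ub[i]))
      stop("simplex backend requires finite row bounds");
    if (row_lb[i] > row_ub[i]) stop("row lower bound exceeds upper bound");
    int j = nx + i;            // slack: A x - w = 0
    sp.lo[j] = row_lb[i]; sp.hi[j] = row_ub[i];
    sp.t(i, j) = -1.0;
  }
  // start nonbasic at the bound of least magnitude
  for (int j = 0; j < sp.n; ++j) {
    if (std::fabs(sp.lo[j]) <= std::fabs(sp.hi[j])) {
      sp.stat[j] = AT_LOWER; sp.val[j] = sp.lo[j];
    } else {
      sp.stat[j] = AT_UPPER; sp.val[j] = sp.hi[j];
    }
  }
  // residual r_i = -sum_j a_ij val_j ; artificial column sign(r_i)
  std::vector<double> r(m, 0.0);
  for (int j = 0; j < sp.n; ++j) {
    double v = sp.val[j];
    if (v == 0.0) continue;
    for (int i = 0; i < m; ++i) r[i] -= sp.t(i, j) * v;
  }
  for (int i = 0; i < m; ++i) {
    int j = sp.n + i;
    double s = (r[i] >= 0) ? 1.0 : -1.0;
    sp.t(i, j) = s;
    sp.lo[j] = 0.0; sp.hi[j] = INF;
    sp.basis[i] = j; sp.stat[j] = BASIC;
    sp.val[j] = std::fabs(r[i]);
    sp.beta[i] = std::fabs(r[i]);
    // normalize row so the artificial has +1 and beta >= 0
    if (s < 0) {
      double* row = &sp.T[(size_t)i * sp.ntot];
      for (int k = 0; k < sp.ntot; ++k) row[k] = -row[k];
      sp.t(i, j) = 1.0;
    }
  }

  long maxit = 20000L + 200L * (long)(sp.m + sp.n);

  // phase 1: maximize -sum(artificials)
  std::vector<double> c1(sp.ntot, 0.0);
  for (int i = 0; i < m; ++i) c1[sp.n + i] = -1.0;
  int rc = sp.iterate(c1, maxit);
  sp.refresh_beta();
  double infeas = 0.0;
  for (int i = 0; i < m; ++i)
    if (sp.basis[i] >= sp.n) infeas += std::fabs(sp.beta[i]);
  for (int j = sp.n; j < sp.ntot; ++j)
    if (sp.stat[j] != BASIC) infeas += std::fabs(sp.val[j]);
  std::string status;
  NumericVector x(nx);
  double objval = NA_REAL;
  if (rc == 2 || rc == 3) status = "failed";
  else if (infeas > sp.eps_feas) status = "infeasible";
  else {
    // freeze artificials at zero and run phase 2
    for (int j = sp.n; j < sp.ntot; ++j) {
      sp.lo[j] = 0.0; sp.hi[j] = 0.0;
      if (sp.stat[j] != BASIC) sp.val[j] = 0.0;
    }
    std::vector<double> c2(sp.ntot, 0.0);
    double sgn = maximize ? 1.0 : -1.0;
    for (int j = 0; j < nx; ++j) c2[j] = sgn * obj[j];
    rc = sp.iterate(c2, maxit);
    sp.refresh_beta();
    if (rc == 2) status = "failed";
    else if (rc == 3) status = "unbounded";
    else {
      status = "optimal";
      for (int j = 0; j < nx; ++j)
        x[j] = (sp.stat[j] == BASIC) ? NA_REAL : sp.val[j];
      for (int i = 0; i < m; ++i)
        if (sp.basis[i] < nx) x[sp.basis[i]] = sp.beta[i];
      objval = 0.0;
      for (int j = 0; j < nx; ++j) objval += obj[j] * x[j];
    }
  }
  return List::create(_["status"] = status, _["x"] = x,
                      _["objective"] = objval);
}
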