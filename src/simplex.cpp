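// Dense two-phase primal simplex for the small linear programs arising in
// flux balance analysis:  optimize c'v  s.t.  Aeq v = beq,  lb <= v <= ub.
//
// Problems here are tiny (tens of variables), so a dense tableau with
// Bland's anti-cycling rule is both fast enough and fully deterministic:
// ties are broken by variable index, which follows the model's reaction
// order. Determinism matters downstream (reproducible exchange networks).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double TOL = 1e-9;

// Solve: min  cost' z   s.t.  T z = b (b >= 0), z >= 0, starting from the
// given basis (one basic column per row). Tableau is modified in place.
// Columns in [scanN, N) are skipped during pricing (used to freeze
// non-basic artificials out of phase 2). Returns 0 optimal, 1 unbounded.
//
// Pricing is Dantzig (most negative reduced cost) for speed, switching to
// Bland's smallest-index rule after a burn-in to guarantee termination on
// degenerate instances.
static int simplex_core(std::vector<double> &T, int M, int N, int scanN,
                        std::vector<double> &b,
                        const std::vector<double> &cost,
                        std::vector<int> &basis) {
  std::vector<double> y(M);          // basic costs
  const int bland_after = 5 * (M + scanN);
  for (int iter = 0; iter < 20000; ++iter) {
    const bool bland = iter > bland_after;
    // T is kept canonical w.r.t. the basis, so the reduced cost of column j
    // is cost[j] - sum_i cost[basis[i]] * T[i][j].
    for (int i = 0; i < M; ++i) y[i] = cost[basis[i]];
    int enter = -1;
    double most = -TOL;
    for (int j = 0; j < scanN; ++j) {
      double r = cost[j];
      for (int i = 0; i < M; ++i) r -= y[i] * T[(size_t)i * N + j];
      if (bland) {
        if (r < -TOL) { enter = j; break; }
      } else if (r < most) {
        most = r;
        enter = j;
      }
    }
    if (enter < 0) return 0;                  // optimal
    // ratio test, Bland tie-break on basis variable index
    int leave = -1;
    double best = std::numeric_limits<double>::infinity();
    for (int i = 0; i < M; ++i) {
      double a = T[(size_t)i * N + enter];
      if (a > TOL) {
        double ratio = b[i] / a;
        if (ratio < best - TOL ||
            (ratio < best + TOL && (leave < 0 || basis[i] < basis[leave]))) {
          best = ratio;
          leave = i;
        }
      }
    }
    if (leave < 0) return 1;                  // unbounded
    // pivot on (leave, enter)
    double piv = T[(size_t)leave * N + enter];
    for (int j = 0; j < N; ++j) T[(size_t)leave * N + j] /= piv;
    b[leave] /= piv;
    for (int i = 0; i < M; ++i) {
      if (i == leave) continue;
      double f = T[(size_t)i * N + enter];
      if (f != 0.0) {
        for (int j = 0; j < N; ++j)
          T[(size_t)i * N + j] -= f * T[(size_t)leave * N + j];
        b[i] -= f * b[leave];
        if (std::fabs(b[i]) < 1e-12) b[i] = 0.0;
      }
    }
    basis[leave] = enter;
  }
  return 2;                                    // iteration limit (should not happen)
}

// [[Rcpp::export(name = ".solve_lp_cpp")]]
List solve_lp_cpp(NumericVector obj, NumericMatrix Aeq, NumericVector beq,
                  NumericVector lb, NumericVector ub, bool maximize) {
  const int n = obj.size();
  const int m = Aeq.nrow();
  for (int j = 0; j < n; ++j) {
    if (!R_finite(lb[j]) || !R_finite(ub[j]))
      stop("solve_lp: all variable bounds must be finite");
    if (lb[j] > ub[j] + 1e-12)
      return List::create(_["status"] = "infeasible",
                          _["x"] = R_NilValue, _["objval"] = R_NilValue);
  }

  // Shift x = v - lb >= 0; upper-bound rows x_j + s_j = ub_j - lb_j.
  // Skip slack rows for fixed variables (ub == lb): x_j is then forced 0 by
  // its upper-bound row; keep the row anyway for uniform handling.
  const int M = m + n;            // equality rows + bound rows
  const int N = 2 * n;            // x and slack s
  std::vector<double> T((size_t)M * (N + M), 0.0);  // extra M cols: artificials
  std::vector<double> b(M);

  for (int i = 0; i < m; ++i) {
    double rhs = beq[i];
    for (int j = 0; j < n; ++j) rhs -= Aeq(i, j) * lb[j];
    for (int j = 0; j < n; ++j) T[(size_t)i * (N + M) + j] = Aeq(i, j);
    b[i] = rhs;
  }
  for (int j = 0; j < n; ++j) {
    int i = m + j;
    T[(size_t)i * (N + M) + j] = 1.0;
    T[(size_t)i * (N + M) + n + j] = 1.0;
    b[i] = ub[j] - lb[j];
  }
  // make b >= 0
  for (int i = 0; i < M; ++i) {
    if (b[i] < 0) {
      b[i] = -b[i];
      for (int j = 0; j < N; ++j) T[(size_t)i * (N + M) + j] *= -1.0;
    }
  }
  // artificials
  for (int i = 0; i < M; ++i) T[(size_t)i * (N + M) + N + i] = 1.0;

  const int Nfull = N + M;
  std::vector<int> basis(M);
  for (int i = 0; i < M; ++i) basis[i] = N + i;

  // Phase 1
  std::vector<double> cost1(Nfull, 0.0);
  for (int i = 0; i < M; ++i) cost1[N + i] = 1.0;
  int rc = simplex_core(T, M, Nfull, N, b, cost1, basis);
  double art = 0.0;
  for (int i = 0; i < M; ++i) if (basis[i] >= N) art += b[i];
  if (rc != 0 || art > 1e-7)
    return List::create(_["status"] = "infeasible",
                        _["x"] = R_NilValue, _["objval"] = R_NilValue);
  // drive any residual (degenerate) artificials out of the basis
  for (int i = 0; i < M; ++i) {
    if (basis[i] >= N) {
      int enter = -1;
      for (int j = 0; j < N; ++j)
        if (std::fabs(T[(size_t)i * Nfull + j]) > TOL) { enter = j; break; }
      if (enter >= 0) {
        double piv = T[(size_t)i * Nfull + enter];
        for (int j = 0; j < Nfull; ++j) T[(size_t)i * Nfull + j] /= piv;
        b[i] /= piv;
        for (int k = 0; k < M; ++k) {
          if (k == i) continue;
          double f = T[(size_t)k * Nfull + enter];
          if (f != 0.0) {
            for (int j = 0; j < Nfull; ++j)
              T[(size_t)k * Nfull + j] -= f * T[(size_t)i * Nfull + j];
            b[k] -= f * b[i];
          }
        }
        basis[i] = enter;
      }
      // else: redundant zero row; harmless to leave artificial at level 0
    }
  }

  // Phase 2: non-basic artificials are frozen out by restricting the
  // pricing scan to the structural and slack columns; any artificial still
  // in the basis sits at level 0 on a redundant row and stays there.
  std::vector<double> cost2(Nfull, 0.0);
  for (int j = 0; j < n; ++j) cost2[j] = maximize ? -obj[j] : obj[j];
  rc = simplex_core(T, M, Nfull, N, b, cost2, basis);
  if (rc == 1)
    return List::create(_["status"] = "unbounded",
                        _["x"] = R_NilValue, _["objval"] = R_NilValue);
  if (rc != 0)
    return List::create(_["status"] = "iteration_limit",
                        _["x"] = R_NilValue, _["objval"] = R_NilValue);

  NumericVector x(n);
  std::vector<double> z(Nfull, 0.0);
  for (int i = 0; i < M; ++i) z[basis[i]] = b[i];
  double objval = 0.0;
  for (int j = 0; j < n; ++j) {
    x[j] = z[j] + lb[j];
    objval += obj[j] * x[j];
  }
  return List::create(_["status"] = "optimal", _["x"] = x,
                      _["objval"] = objval);
}
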