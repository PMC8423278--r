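// Exact solver for small/medium mixed-integer linear programs:
//   min c'x  s.t.  A x {=,<=} b,  lb <= x <= ub,  x[j] integer for j in intvars.
// Dense bounded-variable primal simplex (two-phase, with the classic
// "flip" substitution x -> u - x for variables nonbasic at their upper
// bound) plus depth-first branch and bound.  Written for the flow and
// untangling models of this package: a few thousand variables at most,
// all data well scaled.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double TOL = 1e-7;     // reduced-cost / pivot tolerance
static const double RTOL = 1e-9;    // ratio-test tolerance
static const double BIG = 1e30;

struct LPOut {
  int status;        // 0 optimal, 1 infeasible, 2 unbounded, 3 iter limit
  double obj;
  vec x;             // structural solution (original space)
};

// Bounded simplex on the tableau.  Variables live in "flipped space":
// every nonbasic variable sits at 0; flipped[j] means x_j = u_j - y_j.
class Tableau {
public:
  mat T;                    // (m+1) x (N+1); last row cost, last col rhs
  uvec basis;               // length m, column index basic in each row
  std::vector<char> flipped, banned, isbasic;
  vec ub;                   // length N (upper bounds in shifted space)
  int m, N;
  int stall = 0;
  bool bland = false;
  long iters = 0;
  vec devex;   // reference weights

  void init_devex() { devex = ones<vec>(N); }

  void flip(int j) {
    // nonbasic j moves between its bounds; u must be finite
    T.col(N) -= ub[j] * T.col(j);
    T.col(j) *= -1.0;
    flipped[j] = !flipped[j];
  }

  void pivot(int r, int j) {
    double piv = T(r, j);
    T.row(r) /= piv;
    vec col = T.col(j);
    col(r) = 0.0;
    // column-wise rank-1 update restricted to nonzeros of the pivot row
    for (int jj = 0; jj <= N; ++jj) {
      if (jj == j) continue;
      double a = T(r, jj);
      if (std::fabs(a) < 1e-13) continue;
      T.col(jj) -= a * col;
    }
    T.col(j).zeros();
    T(r, j) = 1.0;
    isbasic[basis[r]] = 0;
    isbasic[j] = 1;
    basis[r] = j;
  }

  // returns 0 optimal, 2 unbounded, 3 iteration limit
  int run(int maxit) {
    if (devex.n_elem != (uword)N) init_devex();
    for (int it = 0; it < maxit; ++it) {
      ++iters;
      // entering variable (devex pricing)
      int j_in = -1;
      double best = -TOL, bestscore = 0.0;
      for (int j = 0; j < N; ++j) {
        if (isbasic[j] || banned[j]) continue;
        double d = T(m, j);
        if (bland) {
          if (d < -TOL) { j_in = j; break; }
        } else if (d < -TOL) {
          double score = d * d / devex[j];
          if (score > bestscore) { bestscore = score; j_in = j; }
        }
      }
      if (j_in < 0) return 0;

      // ratio test
      double tmax = ub[j_in] < BIG ? ub[j_in] : datum::inf;
      int r_out = -1;
      bool out_at_upper = false;
      for (int i = 0; i < m; ++i) {
        double a = T(i, j_in);
        double lim;
        bool upper;
        if (a > TOL) { lim = T(i, N) / a; upper = false; }
        else if (a < -TOL && ub[basis[i]] < BIG) {
          lim = (ub[basis[i]] - T(i, N)) / (-a); upper = true;
        } else continue;
        if (lim < -RTOL) lim = 0.0;
        if (lim < tmax - RTOL ||
            (lim < tmax + RTOL && r_out >= 0 && bland &&
             basis[i] < basis[r_out])) {
          tmax = lim; r_out = i; out_at_upper = upper;
        }
      }
      if (!std::isfinite(tmax)) return 2;
      if (tmax < RTOL) { if (++stall > 500) bland = true; }
      else { stall = 0; bland = false; }

      if (r_out < 0) {            // entering variable hits its own bound
        flip(j_in);
        continue;
      }
      int leaving = basis[r_out];
      double piv = T(r_out, j_in); // before pivot
      vec colv = T.col(j_in);
      pivot(r_out, j_in);
      if (out_at_upper) flip(leaving);   // leaving variable rests at upper
      // devex update (approximate): w_leave = max(w_enter/piv^2, 1)
      double we = devex[j_in];
      for (int j = 0; j < N; ++j) {
        if (isbasic[j] || banned[j]) continue;
        double a = T(r_out, j);
        if (std::fabs(a) > 1e-12) {
          double cand = a * a * we;
          if (cand > devex[j]) devex[j] = cand;
        }
      }
      devex[leaving] = std::max(we / (piv * piv), 1.0);
    }
    return 3;
  }
};

// One LP solve.  sense: 0 '=', 1 '<='.
static LPOut lp_solve(const vec& cost, const mat& A, const ivec& sense,
                      const vec& b, const vec& lb, const vec& ub_in,
                      int maxit = 200000) {
  int m = A.n_rows, n = A.n_cols;
  LPOut out; out.status = 1; out.obj = datum::inf; out.x = zeros<vec>(n);

  // shift x = lb + y
  vec u = ub_in - lb;
  vec bb = b - A * lb;
  for (int j = 0; j < n; ++j) {
    if (u[j] < -1e-9) return out;          // empty box
    if (u[j] < 0) u[j] = 0;
  }

  // columns: structural n, then one slack per '<=' row, then artificials
  int nslack = 0;
  for (int i = 0; i < m; ++i) if (sense[i] == 1) nslack++;
  // count artificials after sign normalisation
  std::vector<int> slackcol(m, -1);
  std::vector<int> rowsign(m, 1);
  for (int i = 0; i < m; ++i)
    if (sense[i] == 1 && bb[i] < 0) rowsign[i] = -1;   // slack would be infeasible
  for (int i = 0; i < m; ++i)
    if (sense[i] == 0 && bb[i] < 0) rowsign[i] = -1;
  int nart = 0;
  for (int i = 0; i < m; ++i) {
    bool needart = (sense[i] == 0) || (rowsign[i] == -1);
    if (needart) nart++;
  }
  int N = n + nslack + nart;

  Tableau tb;
  tb.m = m; tb.N = N;
  tb.T = zeros<mat>(m + 1, N + 1);
  tb.basis = zeros<uvec>(m);
  tb.flipped.assign(N, 0);
  tb.banned.assign(N, 0);
  tb.isbasic.assign(N, 0);
  tb.ub = vec(N); tb.ub.fill(BIG);
  for (int j = 0; j < n; ++j) tb.ub[j] = std::isfinite(u[j]) ? u[j] : BIG;

  int sc = n, ac = n + nslack;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) tb.T(i, j) = rowsign[i] * A(i, j);
    tb.T(i, N) = rowsign[i] * bb[i];
    if (sense[i] == 1) {
      slackcol[i] = sc;
      tb.T(i, sc) = rowsign[i];        // slack: +1 normally, -1 on flipped rows
      sc++;
    }
    bool needart = (sense[i] == 0) || (rowsign[i] == -1);
    if (needart) {
      tb.T(i, ac) = 1.0;
      tb.basis[i] = ac; tb.isbasic[ac] = 1;
      ac++;
    } else {
      tb.basis[i] = slackcol[i]; tb.isbasic[slackcol[i]] = 1;
    }
  }

  // ---- phase 1 ----
  if (nart > 0) {
    // cost row: minimise sum of artificials; reduced costs need basis sweep
    for (int j = n + nslack; j < N; ++j) tb.T(m, j) = 1.0;
    for (int i = 0; i < m; ++i)
      if ((int)tb.basis[i] >= n + nslack) tb.T.row(m) -= tb.T.row(i);
    int st = tb.run(maxit);
    if (st == 3) { out.status = 3; return out; }
    double ph1 = -tb.T(m, N);
    // recompute from rhs for robustness
    double ph1b = 0;
    for (int i = 0; i < m; ++i)
      if ((int)tb.basis[i] >= n + nslack) ph1b += tb.T(i, N);
    if (std::min(ph1, ph1b) > 1e-6 && ph1b > 1e-6) { out.status = 1; return out; }
    // pivot remaining artificials out where possible, then ban them
    for (int i = 0; i < m; ++i) {
      if ((int)tb.basis[i] < n + nslack) continue;
      int jj = -1;
      for (int j = 0; j < n + nslack; ++j)
        if (!tb.isbasic[j] && std::fabs(tb.T(i, j)) > 1e-6) { jj = j; break; }
      if (jj >= 0) tb.pivot(i, jj);
    }
    for (int j = n + nslack; j < N; ++j) tb.banned[j] = 1;
  }

  // ---- phase 2 ----
  // effective costs in flipped space; constant term from flips
  vec chat = zeros<vec>(N);
  double cconst = 0.0;
  for (int j = 0; j < n; ++j) {
    if (tb.flipped[j]) { chat[j] = -cost[j]; cconst += cost[j] * tb.ub[j]; }
    else chat[j] = cost[j];
  }
  tb.T.row(m).zeros();
  for (int j = 0; j < N; ++j) tb.T(m, j) = chat[j];
  for (int i = 0; i < m; ++i) {
    double cb = chat[tb.basis[i]];
    if (cb != 0.0) tb.T.row(m) -= cb * tb.T.row(i);
  }
  tb.stall = 0; tb.bland = false;
  int st = tb.run(maxit);
  if (st == 2) { out.status = 2; return out; }
  if (st == 3) { out.status = 3; return out; }

  vec y = zeros<vec>(N);
  for (int i = 0; i < m; ++i) y[tb.basis[i]] = tb.T(i, N);
  for (int j = 0; j < N; ++j)
    if (tb.flipped[j]) y[j] = (tb.ub[j] < BIG ? tb.ub[j] : 0) - y[j];
  out.x = y.head(n) + lb;
  // clamp tiny negatives
  for (int j = 0; j < n; ++j) {
    if (out.x[j] < lb[j]) out.x[j] = lb[j];
    if (std::isfinite(ub_in[j]) && out.x[j] > ub_in[j]) out.x[j] = ub_in[j];
  }
  out.obj = dot(cost, out.x);
  out.status = 0;
  return out;
}

// [[Rcpp::export(name = ".lp_solve_cpp")]]
Rcpp::List lp_solve_cpp(const arma::vec& cost, const arma::mat& A,
                        const arma::ivec& sense, const arma::vec& b,
                        const arma::vec& lb, const arma::vec& ub) {
  LPOut r = lp_solve(cost, A, sense, b, lb, ub);
  return Rcpp::List::create(Rcpp::Named("status") = r.status,
                            Rcpp::Named("objective") = r.obj,
                            Rcpp::Named("x") = r.x);
}

struct BBNode { vec lb, ub; double bound; };

// [[Rcpp::export(name = ".milp_solve_cpp")]]
Rcpp::List milp_solve_cpp(const arma::vec& cost, const arma::mat& A,
                          const arma::ivec& sense, const arma::vec& b,
                          const arma::vec& lb0, const arma::vec& ub0,
                          const arma::uvec& intvar, int max_nodes = 50000) {
  int n = A.n_cols;
  std::vector<char> isint(n, 0);
  for (uword k = 0; k < intvar.n_elem; ++k) isint[intvar[k]] = 1;

  double best = datum::inf;
  vec bestx;
  int status = 1;  // infeasible until an incumbent is found
  bool limit_hit = false;

  std::vector<BBNode> stack;
  stack.push_back({lb0, ub0, -datum::inf});
  int nodes = 0;

  while (!stack.empty()) {
    if (++nodes > max_nodes) { limit_hit = true; break; }
    BBNode nd = stack.back(); stack.pop_back();
    if (nd.bound > best - 1e-9) continue;
    LPOut r = lp_solve(cost, A, sense, b, nd.lb, nd.ub);
    if (r.status == 1) continue;                // infeasible branch
    if (r.status != 0) { limit_hit = true; continue; }
    if (r.obj > best - 1e-9) continue;
    // most fractional integer variable
    int jf = -1; double fbest = 1e-6;
    for (int j = 0; j < n; ++j) {
      if (!isint[j]) continue;
      double v = r.x[j];
      double f = std::fabs(v - std::round(v));
      if (f > fbest) { fbest = f; jf = j; }
    }
    if (jf < 0) {                                // integral
      // round defensively
      vec xi = r.x;
      for (int j = 0; j < n; ++j) if (isint[j]) xi[j] = std::round(xi[j]);
      double obj = dot(cost, xi);
      if (obj < best - 1e-9) { best = obj; bestx = xi; status = 0; }
      continue;
    }
    double v = r.x[jf];
    double fl = std::floor(v), ce = std::ceil(v);
    BBNode down = nd, up = nd;
    down.ub[jf] = fl; down.bound = r.obj;
    up.lb[jf] = ce;   up.bound = r.obj;
    // explore the nearer side first (push it last)
    if (v - fl < ce - v) { stack.push_back(up); stack.push_back(down); }
    else { stack.push_back(down); stack.push_back(up); }
  }

  if (status != 0 && limit_hit) status = 3;
  return Rcpp::List::create(Rcpp::Named("status") = status,
                            Rcpp::Named("objective") = best,
                            Rcpp::Named("x") = (status == 0 || bestx.n_elem)
                              ? Rcpp::wrap(bestx) : Rcpp::wrap(vec()),
                            Rcpp::Named("nodes") = nodes);
}
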