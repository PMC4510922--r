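#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Target predicate over a decoded 0/1 assignment.
// type 0: none; 1: CNF (flat signed literals, offsets per clause);
// 2: valence (flat variable indices, offsets per group, required sums).
static bool target_ok(int type, const std::vector<int>& flat,
                      const std::vector<int>& off,
                      const std::vector<int>& sums,
                      const std::vector<int>& x) {
  if (type == 0) return false;
  if (type == 1) {
    for (size_t c = 0; c + 1 < off.size(); ++c) {
      bool sat = false;
      for (int k = off[c]; k < off[c + 1]; ++k) {
        int lit = flat[k];
        int v = lit > 0 ? lit : -lit;
        if ((lit > 0) == (x[v - 1] == 1)) { sat = true; break; }
      }
      if (!sat) return false;
    }
    return true;
  }
  for (size_t g = 0; g + 1 < off.size(); ++g) {
    int s = 0;
    for (int k = off[g]; k < off[g + 1]; ++k) s += x[flat[k] - 1];
    if (s != sums[g]) return false;
  }
  return true;
}

// Synchronous bounceback-controlled dynamics.
// Unit (i,v) lives at flat index 2*(i-1)+v (0-based here; 1-based from R).
// Per evaluated step t: decode x(t) from X(t); combined signals s(t) by
// noisy-OR over firing rules; stability flag; target / persistence checks;
// then one RNG draw per unit (in unit order) to sample supply and update X.
// [[Rcpp::export]]
List amoeba_run_cpp(int n_vars,
                    IntegerVector cond_flat, IntegerVector cond_off,
                    IntegerVector rule_target, NumericVector rule_intensity,
                    double p_free, double p_blocked,
                    int max_steps, int stability_window,
                    IntegerVector x0, IntegerVector X0,
                    int target_type, IntegerVector t_flat,
                    IntegerVector t_off, IntegerVector t_sums,
                    int stop_mode, bool record) {
  const int nu = 2 * n_vars;
  const int nr = rule_target.size();
  std::vector<int> X(X0.begin(), X0.end());
  std::vector<int> x(x0.begin(), x0.end());
  std::vector<int> xprev(x);
  std::vector<double> keep(nu);
  std::vector<int> tflat(t_flat.begin(), t_flat.end());
  std::vector<int> toff(t_off.begin(), t_off.end());
  std::vector<int> tsums(t_sums.begin(), t_sums.end());

  std::vector<int> ev_steps;
  std::vector<int> ev_assign;       // row-major n_vars per event
  std::vector<char> stable_log;
  if (record) { ev_steps.reserve(256); stable_log.reserve(max_steps); }

  int first_sat = -1, first_window = -1;
  std::vector<int> found;
  int runlen = 0, steps = 0;
  RNGScope scope;

  for (int t = 0; t < max_steps; ++t) {
    // decode x(t) from X(t), keeping previous value on ambiguity
    xprev = x;
    for (int i = 0; i < n_vars; ++i) {
      int X0i = X[2 * i], X1i = X[2 * i + 1];
      if (X0i == 1 && X1i <= 0) x[i] = 0;
      else if (X1i == 1 && X0i <= 0) x[i] = 1;
    }
    bool changed = (t == 0) || (x != xprev);
    runlen = changed && t > 0 ? 1 : runlen + 1;
    if (t == 0) runlen = 1;

    // combined signals (noisy-OR of firing rules per target)
    std::fill(keep.begin(), keep.end(), 1.0);
    for (int r = 0; r < nr; ++r) {
      bool fire = true;
      for (int k = cond_off[r]; k < cond_off[r + 1]; ++k)
        if (X[cond_flat[k] - 1] != 1) { fire = false; break; }
      if (fire) keep[rule_target[r] - 1] *= 1.0 - rule_intensity[r];
    }

    // stable: every X=1 unit unblocked, every X<=0 unit blocked, and every
    // variable expressed (at least one unit at 1; excludes stale decodes)
    bool stable = true;
    for (int u = 0; u < nu; ++u) {
      double s = 1.0 - keep[u];
      bool ok = (X[u] == 1 && s == 0.0) || (X[u] <= 0 && s > 0.0);
      if (!ok) { stable = false; break; }
    }
    if (stable)
      for (int i = 0; i < n_vars; ++i)
        if (X[2 * i] != 1 && X[2 * i + 1] != 1) { stable = false; break; }

    if (record) {
      stable_log.push_back(stable ? 1 : 0);
      if (changed) {
        ev_steps.push_back(t);
        ev_assign.insert(ev_assign.end(), x.begin(), x.end());
      }
    }

    bool sat = target_ok(target_type, tflat, toff, tsums, x);
    if (sat && first_sat < 0) first_sat = t;
    if (sat && runlen >= stability_window && first_window < 0) {
      first_window = t;
      found = x;
    }
    steps = t + 1;
    if (stop_mode == 1 && sat) break;
    if (stop_mode == 2 && first_window >= 0) break;

    // supply and saturating accumulation; one draw per unit, unit order
    for (int u = 0; u < nu; ++u) {
      double s = 1.0 - keep[u];
      double p = (1.0 - s) * p_free + s * p_blocked;
      int r = unif_rand() < p ? 1 : 0;
      if (r == 1 && X[u] < 1) X[u] += 1;
      else if (r == 0 && X[u] > -1) X[u] -= 1;
    }
  }

  List out = List::create(
    _["steps"] = steps,
    _["first_target_step"] = first_sat,
    _["first_window_step"] = first_window,
    _["found"] = found.empty() ? R_NilValue
                 : (SEXP)IntegerVector(found.begin(), found.end()),
    _["X_final"] = IntegerVector(X.begin(), X.end()),
    _["x_final"] = IntegerVector(x.begin(), x.end()));
  if (record) {
    int ne = ev_steps.size();
    IntegerMatrix ea(ne, n_vars);
    for (int e = 0; e < ne; ++e)
      for (int i = 0; i < n_vars; ++i) ea(e, i) = ev_assign[e * n_vars + i];
    out["event_steps"] = IntegerVector(ev_steps.begin(), ev_steps.end());
    out["event_assignments"] = ea;
    out["stable"] = LogicalVector(stable_log.begin(), stable_log.end());
  } else {
    out["event_steps"] = R_NilValue;
    out["event_assignments"] = R_NilValue;
    out["stable"] = R_NilValue;
  }
  return out;
}

static inline int pick(int m) {
  int k = (int)(unif_rand() * m);
  return k >= m ? m - 1 : k;
}

// Pure random-walk WalkSAT with incremental true-literal counts.
// greedy_p > 0 mixes in break-count-minimising picks (off by default).
// [[Rcpp::export]]
List walksat_run_cpp(int n_vars, IntegerVector cl_flat, IntegerVector cl_off,
                     int max_flips, IntegerVector x0, double greedy_p) {
  const int ncl = cl_off.size() - 1;
  std::vector<int> x(x0.begin(), x0.end());
  std::vector<int> cnt(ncl, 0);
  // occurrence lists: clauses containing each variable (with sign)
  std::vector<std::vector<int>> occ(n_vars);       // clause index
  std::vector<std::vector<int>> occ_sign(n_vars);  // +1 / -1
  for (int c = 0; c < ncl; ++c)
    for (int k = cl_off[c]; k < cl_off[c + 1]; ++k) {
      int lit = cl_flat[k];
      int v = (lit > 0 ? lit : -lit) - 1;
      occ[v].push_back(c);
      occ_sign[v].push_back(lit > 0 ? 1 : -1);
    }
  std::vector<int> unsat;            // clause indices with cnt == 0
  std::vector<int> pos(ncl, -1);     // position in unsat, or -1
  for (int c = 0; c < ncl; ++c) {
    for (int k = cl_off[c]; k < cl_off[c + 1]; ++k) {
      int lit = cl_flat[k];
      int v = (lit > 0 ? lit : -lit) - 1;
      if ((lit > 0) == (x[v] == 1)) cnt[c]++;
    }
    if (cnt[c] == 0) { pos[c] = unsat.size(); unsat.push_back(c); }
  }

  RNGScope scope;
  int flips = 0;
  auto flip_var = [&](int v) {
    x[v] ^= 1;
    for (size_t j = 0; j < occ[v].size(); ++j) {
      int c = occ[v][j];
      bool now_true = (occ_sign[v][j] > 0) == (x[v] == 1);
      if (now_true) {
        if (cnt[c]++ == 0) {  // leaves unsat set
          int p = pos[c], last = unsat.back();
          unsat[p] = last; pos[last] = p;
          unsat.pop_back(); pos[c] = -1;
        }
      } else {
        if (--cnt[c] == 0) { pos[c] = unsat.size(); unsat.push_back(c); }
      }
    }
  };
  auto break_count = [&](int v) {
    int b = 0;
    for (size_t j = 0; j < occ[v].size(); ++j) {
      int c = occ[v][j];
      bool lit_true = (occ_sign[v][j] > 0) == (x[v] == 1);
      if (lit_true && cnt[c] == 1) b++;
    }
    return b;
  };

  while (flips < max_flips && !unsat.empty()) {
    int c = unsat[pick((int)unsat.size())];
    int len = cl_off[c + 1] - cl_off[c];
    int v;
    if (greedy_p > 0.0 && unif_rand() < greedy_p) {
      int best = -1, bestb = INT_MAX;
      for (int k = cl_off[c]; k < cl_off[c + 1]; ++k) {
        int lit = cl_flat[k];
        int vv = (lit > 0 ? lit : -lit) - 1;
        int b = break_count(vv);
        if (b < bestb) { bestb = b; best = vv; }
      }
      v = best;
    } else {
      int lit = cl_flat[cl_off[c] + pick(len)];
      v = (lit > 0 ? lit : -lit) - 1;
    }
    flip_var(v);
    flips++;
  }
  return List::create(_["solved"] = unsat.empty(),
                      _["flips"] = flips,
                      _["assignment"] = IntegerVector(x.begin(), x.end()));
}
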