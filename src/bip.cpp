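#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact solver for pure 0/1 integer programs by depth-first branch and bound
// with constraint bound propagation. All coefficients, right-hand sides and
// objective terms are integers; every variable is binary. This is the narrow
// back end behind solve_ilp(); determinism matters more than raw speed here
// (fixed branching order, first-found incumbent kept among ties).

namespace {

struct Constraint {
  std::vector<int> idx;   // 0-based variable indices
  std::vector<int> coef;  // nonzero integer coefficients
  int sense;              // 0: >=, 1: <=
  long rhs;
};

struct Solver {
  int n;
  std::vector<Constraint> cons;
  std::vector<long> obj;
  long node_limit;
  long nodes;
  bool have_incumbent;
  long best_obj;
  std::vector<int> best_val;
  bool limit_hit;

  Solver() : n(0), node_limit(0), nodes(0), have_incumbent(false),
             best_obj(0), limit_hit(false) {}

  // Fixpoint propagation over constraint activity bounds. Returns false on
  // conflict; forces variables whose opposite value would make some
  // constraint unsatisfiable.
  bool propagate(std::vector<int>& val) {
    bool changed = true;
    while (changed) {
      changed = false;
      for (std::size_t ci = 0; ci < cons.size(); ++ci) {
        const Constraint& c = cons[ci];
        long lo = 0, hi = 0;
        for (std::size_t k = 0; k < c.idx.size(); ++k) {
          int v = val[c.idx[k]];
          int co = c.coef[k];
          if (v >= 0) {
            lo += (long)co * v;
            hi += (long)co * v;
          } else {
            if (co < 0) lo += co; else hi += co;
          }
        }
        if (c.sense == 0) {  // >= rhs
          if (hi < c.rhs) return false;
          if (lo >= c.rhs) continue;
          for (std::size_t k = 0; k < c.idx.size(); ++k) {
            int j = c.idx[k];
            if (val[j] >= 0) continue;
            int co = c.coef[k];
            if (co > 0 && hi - co < c.rhs) { val[j] = 1; changed = true; }
            else if (co < 0 && hi + co < c.rhs) { val[j] = 0; changed = true; }
          }
        } else {             // <= rhs
          if (lo > c.rhs) return false;
          if (hi <= c.rhs) continue;
          for (std::size_t k = 0; k < c.idx.size(); ++k) {
            int j = c.idx[k];
            if (val[j] >= 0) continue;
            int co = c.coef[k];
            if (co > 0 && lo + co > c.rhs) { val[j] = 0; changed = true; }
            else if (co < 0 && lo - co > c.rhs) { val[j] = 1; changed = true; }
          }
        }
      }
    }
    return true;
  }

  long lower_bound(const std::vector<int>& val) const {
    long b = 0;
    for (int j = 0; j < n; ++j) {
      if (val[j] >= 0) b += obj[j] * val[j];
      else if (obj[j] < 0) b += obj[j];
    }
    return b;
  }

  void search(std::vector<int> val) {
    if (limit_hit) return;
    if (++nodes > node_limit) { limit_hit = true; return; }
    if (!propagate(val)) return;
    long lb = lower_bound(val);
    if (have_incumbent && lb >= best_obj) return;
    int j = -1;
    for (int k = 0; k < n; ++k) {
      if (val[k] < 0) { j = k; break; }
    }
    if (j < 0) {
      best_obj = lb;
      best_val = val;
      have_incumbent = true;
      return;
    }
    int first = obj[j] > 0 ? 0 : 1;
    for (int t = 0; t < 2; ++t) {
      std::vector<int> nv = val;
      nv[j] = (t == 0) ? first : 1 - first;
      search(nv);
      if (limit_hit) return;
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".bip_solve_cpp")]]
List bip_solve_cpp(int n_vars, List cons_idx, List cons_coef,
                   IntegerVector cons_sense, NumericVector cons_rhs,
                   NumericVector objective, IntegerVector fixings,
                   double node_limit) {
  Solver s;
  s.n = n_vars;
  s.obj.resize(n_vars);
  for (int j = 0; j < n_vars; ++j) s.obj[j] = (long)objective[j];
  s.node_limit = (long)node_limit;
  int m = cons_idx.size();
  for (int i = 0; i < m; ++i) {
    IntegerVector ix = cons_idx[i];
    IntegerVector co = cons_coef[i];
    Constraint a;
    a.idx = as<std::vector<int> >(ix);
    a.coef = as<std::vector<int> >(co);
    a.rhs = (long)cons_rhs[i];
    int sense = cons_sense[i];
    if (sense == 2) {  // equality: split
      a.sense = 0; s.cons.push_back(a);
      a.sense = 1; s.cons.push_back(a);
    } else {
      a.sense = sense;
      s.cons.push_back(a);
    }
  }
  std::vector<int> val(n_vars, -1);
  for (int j = 0; j < n_vars; ++j) {
    if (fixings[j] != NA_INTEGER && fixings[j] >= 0) val[j] = fixings[j];
  }
  s.search(val);
  if (s.limit_hit) {
    return List::create(_["status"] = "limit", _["nodes"] = (double)s.nodes);
  }
  if (!s.have_incumbent) {
    return List::create(_["status"] = "infeasible", _["nodes"] = (double)s.nodes);
  }
  return List::create(
      _["status"] = "optimal",
      _["objective"] = (double)s.best_obj,
      _["assignment"] = IntegerVector(s.best_val.begin(), s.best_val.end()),
      _["nodes"] = (double)s.nodes);
}
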