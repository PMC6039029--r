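// Dynamic-programming "circuit" over derivation requirements.
//
// A node is a canonical set of parallel constraints; each constraint is a
// pair (entry position, target point run), all runs of equal length b. A
// derivation of the node is a single program tree whose execution satisfies
// every constraint simultaneously (the shared block of a repetition must
// explain all of its cycles at once). Edges are the grammar decompositions:
// an atomic leaf (b == 1), a binary concatenation split, or a repetition
// (REP0/REP1/REP2, the latter two once per atomic parameter). Distinct
// derivations of the root correspond one-to-one to distinct programs that
// compute the observed sequence from the anchor, so the same circuit yields
// exact counts (sum-product with unit weights), inside probabilities
// (theta-weighted sum-product), minimal description length (min-plus), and
// exact posterior samples of programs (stochastic backtracking).

#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Builder {
  const int* atom;   // column-major nsym x 8
  int nsym;
  int rep_lo, rep_hi;
  int max_nodes;
  std::unordered_map<std::string, int> memo;
  std::vector<int> node_b;
  std::vector<int> eparent, ec1, ec2, ekind, esym, en;

  int amap(int s, int p) const { return atom[s + nsym * p]; }

  void add_edge(int parent, int c1, int c2, int kind, int sym, int n) {
    eparent.push_back(parent);
    ec1.push_back(c1);
    ec2.push_back(c2);
    ekind.push_back(kind);
    esym.push_back(sym);
    en.push_back(n);
  }

  // cs: each string = entry char followed by b target chars ('0'..'7')
  int build(std::vector<std::string> cs) {
    std::sort(cs.begin(), cs.end());
    cs.erase(std::unique(cs.begin(), cs.end()), cs.end());
    std::string key;
    for (const auto& s : cs) { key += s; key += ';'; }
    auto it = memo.find(key);
    if (it != memo.end()) return it->second;

    const int b = (int)cs[0].size() - 1;
    const int id = (int)node_b.size() + 1;
    memo.emplace(std::move(key), id);
    node_b.push_back(b);
    if ((int)node_b.size() > max_nodes)
      stop("enumeration state space exceeded max_nodes");

    if (b == 1) {
      for (int a = 0; a < nsym; ++a) {
        bool ok = true;
        for (const auto& c : cs)
          if (amap(a, c[0] - '0') != c[1] - '0') { ok = false; break; }
        if (ok) add_edge(id, 0, 0, 1, a, 0);
      }
      return id;
    }

    // binary concatenation splits (all association orders arise from the
    // recursion itself, since each side is again decomposed in every way)
    for (int sp = 1; sp < b; ++sp) {
      std::vector<std::string> L, R;
      L.reserve(cs.size());
      R.reserve(cs.size());
      for (const auto& c : cs) {
        L.push_back(c.substr(0, sp + 1));
        std::string r;
        r += c[sp];                 // last point of the left part
        r += c.substr(sp + 1);
        R.push_back(std::move(r));
      }
      int c1 = build(std::move(L));
      int c2 = build(std::move(R));
      add_edge(id, c1, c2, 2, -1, 0);
    }

    // repetitions: n cycles of a shared block of length b / n
    for (int n = std::max(2, rep_lo); n <= rep_hi; ++n) {
      if (b % n != 0) continue;
      const int bl = b / n;

      { // REP0: position threads through, cycle entries come from the target
        std::vector<std::string> ch;
        ch.reserve(cs.size() * n);
        for (const auto& c : cs)
          for (int cy = 0; cy < n; ++cy) {
            std::string s;
            s += (cy == 0) ? c[0] : c[cy * bl];
            s += c.substr(cy * bl + 1, bl);
            ch.push_back(std::move(s));
          }
        int c1 = build(std::move(ch));
        add_edge(id, c1, 0, 3, -1, n);
      }

      // REP1<param>: cycle starts are param-iterated from the entry
      for (int a = 0; a < nsym; ++a) {
        std::vector<std::string> ch;
        ch.reserve(cs.size() * n);
        for (const auto& c : cs) {
          int start = c[0] - '0';
          for (int cy = 0; cy < n; ++cy) {
            std::string s;
            s += (char)('0' + start);
            s += c.substr(cy * bl + 1, bl);
            ch.push_back(std::move(s));
            start = amap(a, start);
          }
        }
        int c1 = build(std::move(ch));
        add_edge(id, c1, 0, 4, a, n);
      }

      // REP2<param>: later cycles are pointwise images of the previous one;
      // only cycle 1 is executed, so the block explains cycle 1 alone
      for (int a = 0; a < nsym; ++a) {
        bool ok = true;
        for (const auto& c : cs) {
          for (int cy = 1; cy < n && ok; ++cy)
            for (int j = 0; j < bl; ++j)
              if (c[cy * bl + 1 + j] - '0' !=
                  amap(a, c[(cy - 1) * bl + 1 + j] - '0')) {
                ok = false;
                break;
              }
          if (!ok) break;
        }
        if (!ok) continue;
        std::vector<std::string> ch;
        ch.reserve(cs.size());
        for (const auto& c : cs) {
          std::string s;
          s += c[0];
          s += c.substr(1, bl);
          ch.push_back(std::move(s));
        }
        int c1 = build(std::move(ch));
        add_edge(id, c1, 0, 5, a, n);
      }
    }
    return id;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_build_circuit(int anchor, IntegerVector sequence,
                       IntegerMatrix atom_table, int rep_lo, int rep_hi,
                       int max_nodes) {
  Builder b;
  b.atom = INTEGER(atom_table);
  b.nsym = atom_table.nrow();
  b.rep_lo = rep_lo;
  b.rep_hi = rep_hi;
  b.max_nodes = max_nodes;
  std::string root_c;
  root_c += (char)('0' + anchor);
  for (int i = 0; i < sequence.size(); ++i)
    root_c += (char)('0' + sequence[i]);
  int root = b.build({root_c});
  return List::create(
    _["root"] = root,
    _["node_b"] = wrap(b.node_b),
    _["parent"] = wrap(b.eparent),
    _["c1"] = wrap(b.ec1),
    _["c2"] = wrap(b.ec2),
    _["kind"] = wrap(b.ekind),
    _["sym"] = wrap(b.esym),   // 0-based atomic index, -1 if none
    _["n"] = wrap(b.en));
}

// Sum-product pass: edges must be ordered so that children are evaluated
// before parents (any order of non-decreasing parent run length works).
// [[Rcpp::export]]
NumericVector cpp_eval_sum(int n_nodes, IntegerVector eorder,
                           IntegerVector parent, IntegerVector c1,
                           IntegerVector c2, NumericVector w) {
  NumericVector v(n_nodes);
  for (int k = 0; k < eorder.size(); ++k) {
    const int e = eorder[k] - 1;
    double x = w[e];
    if (c1[e] > 0) x *= v[c1[e] - 1];
    if (c2[e] > 0) x *= v[c2[e] - 1];
    v[parent[e] - 1] += x;
  }
  return v;
}

// Min-plus pass for description length.
// [[Rcpp::export]]
NumericVector cpp_eval_min(int n_nodes, IntegerVector eorder,
                           IntegerVector parent, IntegerVector c1,
                           IntegerVector c2, NumericVector cost) {
  NumericVector v(n_nodes, R_PosInf);
  for (int k = 0; k < eorder.size(); ++k) {
    const int e = eorder[k] - 1;
    double x = cost[e];
    if (c1[e] > 0) x += v[c1[e] - 1];
    if (c2[e] > 0) x += v[c2[e] - 1];
    if (x < v[parent[e] - 1]) v[parent[e] - 1] = x;
  }
  return v;
}

// Stochastic backtracking: draw one derivation of the root with probability
// proportional to its weight, given the inside values v. Edges must be
// grouped by parent via CSR (node_ptr, eidx). Returns chosen edge ids in
// depth-first preorder (left child expanded before right).
// [[Rcpp::export]]
IntegerVector cpp_sample_edges(int root, IntegerVector node_ptr,
                               IntegerVector eidx, IntegerVector c1,
                               IntegerVector c2, NumericVector w,
                               NumericVector v) {
  std::vector<int> out;
  std::vector<int> stack;
  stack.push_back(root);
  while (!stack.empty()) {
    int node = stack.back();
    stack.pop_back();
    const int lo = node_ptr[node - 1] - 1, hi = node_ptr[node] - 1;
    if (lo >= hi) stop("internal error: sampling reached a dead node");
    double total = v[node - 1];
    if (!(total > 0)) stop("internal error: sampling a zero-mass node");
    double u = unif_rand() * total;
    int chosen = -1;
    double acc = 0.0;
    for (int k = lo; k < hi; ++k) {
      const int e = eidx[k] - 1;
      double x = w[e];
      if (c1[e] > 0) x *= v[c1[e] - 1];
      if (c2[e] > 0) x *= v[c2[e] - 1];
      if (x > 0) chosen = e;   // fp guard: never land on a zero-mass edge
      acc += x;
      if (x > 0 && u <= acc) break;
    }
    if (chosen < 0) stop("internal error: no positive-mass edge");
    out.push_back(chosen + 1);
    // preorder: expand child 1 first
    if (c2[chosen] > 0) stack.push_back(c2[chosen]);
    if (c1[chosen] > 0) stack.push_back(c1[chosen]);
  }
  return wrap(out);
}
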