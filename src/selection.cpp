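// Exact branch-and-bound for coherent k-mer selection:
//   max sum_i w_i y_i  s.t.  |x| <= B,  y_i = AND_{s in V_i} x_s.
// Since y is forced by x, the search runs over window subsets (the windows
// whose constituent sets are added to x).  Pruning uses a valid fractional
// upper bound: each undecided window gets optimistic cost
//   c_i = sum_{s in V_i \ x} 1 / n_s,
// with n_s the multiplicity of s among undecided windows, so that the cost
// of any union is >= the sum of its members' c_i; a fractional knapsack on
// (w_i, c_i) then bounds the achievable remaining weight.  Nodes are
// explored include-first in decreasing w/|V| order, which doubles as a
// greedy incumbent.  If the node cap is hit the best incumbent is returned
// with status "feasible" instead of "optimal".

#include <Rcpp.h>
#include <algorithm>
#include <vector>

namespace {

struct Item {
  double ratio, w, c;
};

class BBSolver {
public:
  int m, S, B;
  std::vector<std::vector<int>> V;   // 0-based kmer ids per window
  std::vector<double> w;
  std::vector<char> x;               // current kmer selection
  std::vector<int> touch;            // selection count per kmer (for pop)
  int used = 0;
  double incweight = 0.0, best = -1.0;
  std::vector<char> bestx;
  long long nodes = 0, cap;
  bool capped = false;

  // scratch for bound(): epoch-stamped multiplicity array
  std::vector<double> mul;
  std::vector<long long> stamp;
  long long epoch = 0;
  std::vector<Item> items;

  BBSolver(const Rcpp::List &Vsets, const Rcpp::NumericVector &weights,
           int S_, int B_, double node_cap)
      : m(Vsets.size()), S(S_), B(B_), w(weights.begin(), weights.end()),
        x(S_, 0), touch(S_, 0), cap((long long)node_cap),
        mul(S_, 0.0), stamp(S_, -1) {
    V.reserve(m);
    for (int i = 0; i < m; ++i) {
      Rcpp::IntegerVector v = Vsets[i];
      V.emplace_back(v.begin(), v.end());
    }
    bestx.assign(S, 0);
  }

  double bound(int d) {
    ++epoch;
    for (int i = d; i < m; ++i)
      for (int s : V[i])
        if (!x[s]) {
          if (stamp[s] != epoch) { stamp[s] = epoch; mul[s] = 0.0; }
          mul[s] += 1.0;
        }
    items.clear();
    double ub = incweight;
    double capacity = (double)(B - used);
    for (int i = d; i < m; ++i) {
      double c = 0.0;
      int miss = 0;
      for (int s : V[i])
        if (!x[s]) { c += 1.0 / mul[s]; ++miss; }
      if (miss == 0) {
        ub += w[i];                    // already covered: free weight
      } else if (miss <= B - used && w[i] > 0.0) {
        items.push_back({w[i] / c, w[i], c});
      }
    }
    std::sort(items.begin(), items.end(),
              [](const Item &a, const Item &b) { return a.ratio > b.ratio; });
    for (const Item &it : items) {
      if (capacity <= 0.0) break;
      if (it.c <= capacity) { ub += it.w; capacity -= it.c; }
      else { ub += it.w * capacity / it.c; capacity = 0.0; }
    }
    return ub;
  }

  void dfs(int d) {
    if (capped) return;
    if (++nodes > cap) { capped = true; return; }
    if (incweight > best) { best = incweight; bestx = x; }
    if (d == m) return;
    if (bound(d) <= best + 1e-12) return;

    // include window d if it fits
    int fresh = 0;
    for (int s : V[d]) if (!x[s]) ++fresh;
    if (used + fresh <= B) {
      for (int s : V[d]) { if (!x[s]) x[s] = 1; ++touch[s]; }
      used += fresh;
      incweight += w[d];
      dfs(d + 1);
      incweight -= w[d];
      used -= fresh;
      for (int s : V[d]) { if (--touch[s] == 0) x[s] = 0; }
    }
    dfs(d + 1);  // exclude branch
  }
};

}  // namespace

// [[Rcpp::export(name = ".bb_select")]]
Rcpp::List bb_select(Rcpp::List Vsets, Rcpp::NumericVector weights,
                     int S, int B, double node_cap) {
  const int m = Vsets.size();

  // static order: decreasing weight density w_i / |V_i|
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::vector<double> dens(m);
  for (int i = 0; i < m; ++i) {
    Rcpp::IntegerVector v = Vsets[i];
    dens[i] = (double)weights[i] / std::max<int>(1, (int)v.size());
  }
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return dens[a] > dens[b]; });
  Rcpp::List Vs(m);
  Rcpp::NumericVector ws(m);
  for (int i = 0; i < m; ++i) {
    Vs[i] = Vsets[ord[i]];
    ws[i] = weights[ord[i]];
  }

  BBSolver solver(Vs, ws, S, B, node_cap);
  solver.dfs(0);

  Rcpp::LogicalVector xsel(S);
  for (int s = 0; s < S; ++s) xsel[s] = solver.bestx[s] != 0;
  return Rcpp::List::create(
      Rcpp::Named("x") = xsel,
      Rcpp::Named("objective") = std::max(0.0, solver.best),
      Rcpp::Named("optimal") = !solver.capped,
      Rcpp::Named("nodes") = (double)solver.nodes);
}
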