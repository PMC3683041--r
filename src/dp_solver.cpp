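#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Exact maximum-weight acyclic selection of one candidate parent set per
// variable, by dynamic programming over vertex subsets:
//   bp[v][S]  = best candidate weight for child v with parents inside S
//   M[S]      = best total weight of a DAG over the variables in S
//   M[S]      = max_{v in S} bp[v][S \ {v}] + M[S \ {v}]   (v = a sink)
// Ties resolved toward the smaller vertex / earlier candidate, so the
// result is deterministic for a fixed input. Feasible for n <= ~20;
// guarded by the caller.
//
// cand_child: 1-based child index per candidate
// cand_mask:  parent-set bitmask (bit v-1 set iff vertex v is a parent)
// weight:     candidate weights (maximized)
// [[Rcpp::export]]
List dp_solve_selection(int n, IntegerVector cand_child,
                        IntegerVector cand_mask, NumericVector weight) {
  const double NEG = -std::numeric_limits<double>::infinity();
  const size_t full = size_t(1) << n;
  const int nc = cand_child.size();

  // best candidate per (v, S): weight and candidate index
  std::vector<std::vector<double> > bp(n, std::vector<double>(full, NEG));
  std::vector<std::vector<int> > bc(n, std::vector<int>(full, -1));

  for (int i = 0; i < nc; ++i) {
    int v = cand_child[i] - 1;
    uint32_t S = (uint32_t)cand_mask[i];
    if (weight[i] > bp[v][S]) {
      bp[v][S] = weight[i];
      bc[v][S] = i;
    }
  }
  for (int v = 0; v < n; ++v) {
    uint32_t vbit = uint32_t(1) << v;
    for (uint32_t S = 0; S < full; ++S) {
      if (S & vbit) continue;
      uint32_t rest = S;
      while (rest) {
        uint32_t low = rest & (~rest + 1u);
        uint32_t sub = S & ~low;
        if (bp[v][sub] > bp[v][S]) {
          bp[v][S] = bp[v][sub];
          bc[v][S] = bc[v][sub];
        }
        rest ^= low;
      }
    }
  }

  std::vector<double> M(full, NEG);
  std::vector<int> sink(full, -1);
  M[0] = 0.0;
  for (uint32_t S = 1; S < full; ++S) {
    uint32_t rest = S;
    while (rest) {
      uint32_t low = rest & (~rest + 1u);
      int v = __builtin_ctz(low);
      uint32_t sub = S ^ low;
      double cand = bp[v][sub] + M[sub];
      if (cand > M[S]) {
        M[S] = cand;
        sink[S] = v;
      }
      rest ^= low;
    }
  }

  // decode: peel sinks off the full set
  uint32_t S = (uint32_t)(full - 1);
  IntegerVector chosen(n);    // candidate index (1-based) per child
  IntegerVector order(n);     // reverse topological order of removal
  int pos = n - 1;
  while (S) {
    int v = sink[S];
    uint32_t sub = S ^ (uint32_t(1) << v);
    chosen[v] = bc[v][sub] + 1;
    order[pos--] = v + 1;
    S = sub;
  }
  return List::create(_["objective"] = M[full - 1],
                      _["chosen"] = chosen,
                      _["order"] = order);
}
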