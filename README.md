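# prognet

Exact score-based learning of **progression networks** — Bayesian networks
tailored to cancer progression — from cross-sectional binary aberration
data.

## The problem

Tumor data are cross-sectional: each patient contributes one tumor assayed
once, recorded as a binary vector of genetic events (for cytogenetic data,
chromosome-arm gains and losses such as `3p-` or `5q+`). The temporal
order in which those aberrations accumulated is not observed, yet it is
the object of interest: later events are favorable to the tumor only
after earlier ones have occurred. `prognet` infers these favorability
relations as a directed acyclic hypergraph over the events, where each
hyperedge connects a child event to the set of parent events that make it
advantageous.

## The model and algorithm

A **k-bounded Bayesian network** restricts every variable to at most
k − 1 parents. Two constrained variants encode progression:

* **Monotone progression network (MPN):** P(child = 1 | parents) ≤ ε
  unless *all* parents have occurred — the conjunctive model; ε = 0
  recovers Conjunctive Bayesian Networks.
* **Semi-monotone progression network (SMPN):** P(child = 1 | parents) ≤ ε
  unless *at least one* parent has occurred.

Learning is score-based with a decomposable score. For a dataset D with m
samples, each candidate hyperedge e = (pa(e) → c) contributes

    w(e) = Σ_u Σ_{x∈{0,1}} N(c = x, pa = u) · log P̂(x | u),

with P̂ the maximum-likelihood estimate N(c = 1, pa = u)/N(pa = u),
capped at ε on the rows the flavor suppresses (constrained ML). The BIC
score subtracts (log m)/2 · 2^|pa(e)| per edge. Because the score
decomposes, the weight of an edge is independent of the rest of the
structure, so all candidates can be scored once into a **selector
hypergraph**: for each event, every parent set of size 0..k−1 (the empty
set standing for artificial *root parents*). Structure learning is then
maximum-weight acyclic selection of one candidate per event, formulated
as an integer program — binary edge variables, continuous order
variables, and big-M ordering constraints that force a topological order
(`build_milp()`, exportable in LP format) — and solved exactly by a
dynamic-programming backend over vertex subsets (default) or a
branch-and-bound backend with time-limit/incumbent semantics. An
exhaustive oracle (`brute_force_learn()`) cross-checks both.

The package also ships the synthetic benchmark around the learner:
a generator of random k-bounded progression networks with
forward sampling (`random_hyperdag()`, `random_cpds()`, `sample_data()`),
recovery metrics on the underlying directed graphs — recovered-edge %,
relative symmetric difference F = |MΔL|/(|M|+|L|), FDR/FNR, and bad-edge
% against a reference partial order — and an ε calibration procedure
(`calibrate_epsilon()`).

## Worked example

Simulate a monotone network over 8 events, sample 1000 tumors, and learn
it back:

```r
library(prognet)
truth <- random_cpds(random_hyperdag(8, 2, seed = 11), flavor = "monotone",
                     epsilon = 0.2, seed = 12)
d <- sample_data(truth, 1000, seed = 13)
fit <- learn_network(d, k = 2, flavor = "monotone", epsilon = 0.2, score = "bic")
fit
#> <pn_fit> monotone network, k = 2, score = bic (epsilon = 0.2)
#>   objective -4507.7295, status optimal, gap 0
#> <hyperdag> 8 vertices, 8 hyperedges
#>   (root) -> v1
#>   ...
#>   v2 -> v6
#>   (root) -> v7
#>   v2 -> v8
```

The objective is the BIC score of the optimal network (sum of selected
edge weights, in nats); `status = "optimal", gap 0` certifies a provably
maximum-score structure. Six events attach to the root (no real
parents); events `v6` and `v8` are each driven by `v2`. Compare against
the generating truth:

```r
edge_metrics(underlying_graph(truth$hyperdag),
             underlying_graph(fit$network$hyperdag))
#>   recovered_pct     F   fdr   fnr n_true_edges n_learned_edges
#> 1           100     0     0     0            2               2
```

Both true directed edges are recovered with no false discoveries
(recovered % = 100, symmetric difference F = 0). `tidy(fit)` lists each
selected hyperedge with its log-likelihood and BIC contribution,
`glance(fit)` gives the one-row fit summary, and `autoplot(fit)` draws
the network. A thin command-line wrapper with `learn`, `simulate`,
`evaluate` and `benchmark` subcommands is installed at
`inst/cli/prognet`.

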