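---
title: "Learning progression networks: models, scores, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning progression networks: models, scores, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prognet)
```

## The model

Cancer progression is a historical process: aberrations accumulate, and
an event can become favorable to the tumor only after earlier events
have occurred. With cross-sectional data — one binary event vector per
tumor — the order is latent and must be inferred. `prognet` models the
joint distribution of the n binary events as a Bayesian network whose
dependence structure is a directed acyclic *hypergraph*: each hyperedge
has one child and a set of parents, and the network is *k-bounded* when
no hyperedge contains more than k vertices (child plus at most k − 1
parents).

Progression is encoded through a constraint on the conditional
probability tables, governed by a single parameter ε ∈ (0, 1):

* **monotone (MPN):** P(child = 1 | parent assignment u) ≤ ε for every
  u except all-ones. The child needs *all* its parents; ε is the
  probability of escaping that requirement. ε = 0 gives a conjunctive
  Bayesian network.
* **semi-monotone (SMPN):** the bound applies only to u = all-zeros —
  the child needs *at least one* parent.
* **general:** no constraint; an ordinary Bayesian network.

ε is the model's only free parameter. Its default, 0.2, is the value at
which learned progression networks of renal-cell-carcinoma cytogenetic
data best respect independently proposed progression pathways; it can
and should be re-calibrated per dataset (see below).

## Scoring and the selector hypergraph

Learning is score-based. For each candidate hyperedge the
maximum-likelihood CPD is estimated by the count ratio
$\hat\theta(u) = N(c{=}1, pa{=}u)/N(pa{=}u)$ and then projected onto the
flavor's constraint set by capping the suppressed rows at ε:
$\min(\hat\theta, \varepsilon)$. Capping (rather than overwriting with
ε) maximizes likelihood subject to the constraint — an estimate already
below the bound is left alone. The edge weight is the data
log-likelihood under the capped CPD with the convention
$0\log 0 = 0$; parent configurations never observed contribute nothing
and carry a flagged placeholder probability of 0. Weights are therefore
finite for any ε > 0, non-positive, and zero exactly when every used
probability is 1. The BIC variant subtracts $(\log m / 2)\,2^{|pa(e)|}$
— the Schwarz penalty with one independent parameter per parent
assignment of a binary child, natural logs throughout.

Because the score decomposes over hyperedges, each candidate's weight is
independent of the remaining structure. The *selector hypergraph*
(`build_selector()`) therefore enumerates, per child, every parent set
of size 0 through k − 1 — $n\sum_{j=0}^{k-1}\binom{n-1}{j}$ candidates —
and scores each once. The empty parent set represents the *root-parent*
edge: artificial parents attached to events that select no real parent.
Root parents carry no data, so a hyperedge's weight ignores them, and
mixed real/root candidates need not be materialized — their weight
equals the root-free version. The output still reports root-attached
hyperedges explicitly, since downstream accounting (the bad-edge
denominator) counts them.

## Exact optimization

Structure learning is maximum-weight selection of one candidate per
child subject to acyclicity. `build_milp()` formulates this as an
integer program: binary variables $x_e$, one per candidate; continuous
order variables $o_v \in [0, n-1]$; per-child equalities
$\sum_{e: c(e)=v} x_e = 1$; and one big-M ordering constraint per
(candidate, parent) pair, $o_{c(e)} - o_u \ge 1 - n(1 - x_e)$. A
selected edge forces its child strictly above each parent in the order,
so no cycle can be selected; a deselected edge leaves the constraint
slack. Order variables stay continuous — integrality adds nothing to
acyclicity and slows solving — and constraints are emitted per parent
rather than aggregated, the tighter relaxation. The program can be
exported in LP format (`write_lp()`).

Two exact backends solve the selection. The default (`backend = "dp"`)
is dynamic programming over vertex subsets: best-parent-set tables
$bp(v, S)$ followed by a best-sink recursion over subsets, implemented
in C++; it certifies optimality (`gap = 0`) and is practical to about 20
events. The alternative (`backend = "bnb"`) is depth-first
branch-and-bound on the $x_e$ variables with a per-child relaxation
bound and incremental cycle detection; it honors `time_limit` and
`mip_gap` and returns the best incumbent with its gap when interrupted,
never silently an empty network. Ties between equal-score structures are
resolved deterministically by enumeration order (children ascending,
parent sets by size then lexicographically; subsets peeled
smallest-vertex-first), so fixed input gives a fixed output. A third,
deliberately independent route — exhaustive enumeration of all
candidate assignments with an acyclicity filter
(`brute_force_learn()`, guarded to n ≤ 7) — exists purely to
cross-check the other two, and the test suite verifies agreement across
flavors and scores.

The all-root-attached assignment is always feasible, so the program is
never infeasible; with the raw likelihood score and no bound on k the
optimum tends toward full connectivity (likelihood never decreases when
parents are added), which is why BIC is the default score.

## What the simulator emulates — and what it does not

`random_hyperdag(n, k)` draws a uniform permutation and lets each vertex
choose a parent-set size uniformly on {0, …, min(k − 1, predecessors)}
and that many distinct predecessors uniformly — acyclic and k-bounded by
construction. `random_cpds()` separates signal from noise: rows the
flavor permits draw from Uniform(0.5, 0.95), suppressed rows from
Uniform(0, ε), general rows from Uniform(0.05, 0.95); parentless events
in progression flavors draw from the signal range so progressions can
start. These ranges are the package's own design (set once, exposed as
arguments): wide enough to vary instance difficulty, with a clear
separation between firing and escape probabilities at the default
ε = 0.2. `sample_data()` forward-samples in topological order,
bit-reproducibly for a fixed seed.

The simulator emulates cross-sectional sampling from a fixed progression
process. It does *not* emulate observation noise (no false
positive/negative aberration calls, no latent-variable layer),
inter-tumor heterogeneity (no mixtures), waiting-time structure, or
missing data. Passing recovery benchmarks on these instances shows the
estimator and optimizer are correct and consistent under the model's own
assumptions — not that real aberration calls satisfy them.

`run_benchmark()` wires generation, learning, and evaluation into a tidy
table with per-cell means and standard deviations. The full study design
(k ∈ {2, 3}, n ∈ {10, 20, 30}, m ∈ {500, 2000, 10000}, 50 replicates) is
expressible but deliberately not the default; the shipped tests and the
acceptance script use n = 10, k = 2 with 10–20 replicates, sizes at
which one exact solve takes well under a second and a whole grid runs in
minutes on one CPU.

## Evaluation metrics

Metrics compare underlying simple digraphs (one directed edge per
parent–child incidence). Recovered % is 100·|M ∩ L|/|M|; the relative
symmetric difference F = (|M∖L| + |L∖M|)/(|M| + |L|) combines
sensitivity and specificity in [0, 1]; FDR = |L∖M|/|L| (defined as 0 for
an empty L) and FNR = |M∖L|/|M|, so recovered % = 100(1 − FNR). All
error when the reference set that normalizes them is empty, rather than
returning a conventional value; `run_benchmark()` records NA for such
(practically non-occurring) replicates.

Against prior biological knowledge, `bad_edge_pct()` counts learned
edges u→v whose reversal is implied by a reference partial order
(v strictly precedes u in the transitive closure). Edges between
incomparable events are not bad — the reference underdetermines them —
and root-attached hyperedges enter the denominator only, diluting the
percentage; both choices make the metric conservative.
`calibrate_epsilon()` learns one network per grid value of ε and picks
the minimizer of the bad-edge percentage, ties toward the smaller (more
conservative) ε. Large ε values effectively dissolve the monotonicity
constraint, which is visible as a rising tail in the calibration curve.

## Numerical and degenerate-input choices

* Natural logarithms everywhere; weights in nats.
* $0\log 0 = 0$; unobserved parent assignments carry probability 0 and a
  flag, never NaN.
* ε must be strictly positive (a capped probability of 0 would give an
  infinite weight); the degenerate conjunctive limit is approached by
  small ε, not ε = 0.
* Vertex indices are 1..n with names in a parallel vector; ties in
  topological sorting and candidate enumeration break by index, so every
  operation is deterministic for fixed input.
* CPD rows are indexed by the parent bitvector with the first stored
  parent as least significant bit; the JSON writer keys rows by explicit
  bitstrings in that order.
* Score ties between structures are real (a single-parent edge with no
  active cap scores identically in both orientations) and are resolved
  arbitrarily-but-deterministically; comparisons in tests therefore
  assert objectives, not structures.

## Known limitations

Binary events only; no missing data, parameter priors, or
noise/latent-variable layer. The dp backend's memory grows as
$n\,2^n$ — beyond ~20 events use `bnb` with a time limit and accept an
incumbent with a reported gap. Score-equivalent orientation ties bound
edge-recovery below 100% even at large sample sizes; this is a property
of the likelihood, not of the optimizer.
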