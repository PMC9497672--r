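---
title: "Feature selection as maximum information flow: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature selection as maximum information flow: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitn)
```

## The problem

Filter feature selection asks for the subset of P predictors that retains the
most information about a class label C, judged without reference to any
downstream classifier. Mutual information (MI) is the natural currency:
I(f; C) measures how much knowing feature f reduces uncertainty about C,
without distributional assumptions and invariantly under monotone
transformations. The classical escape from the combinatorial search over
choose(n, P) subsets is the greedy forward family (mRMR and its relatives),
which builds the subset one feature at a time and can therefore be trapped by
its own early picks, and whose behaviour depends on hand-set scale parameters.

This package implements a nonparametric alternative, MITN-ILP: encode the
whole selection problem as a single maximum-flow mixed-integer linear program
over a *mutual information transfer network*, then solve it with a relative
optimality-gap guarantee. The greedy family is implemented alongside it, in
one generic engine, both as baselines and because the two approaches share
every information-theoretic primitive.

## Information estimation

All estimators are plug-in (maximum-likelihood) estimates over discrete
codes: for a column with empirical level frequencies `p`, entropy is
`H = -sum(p * log2(p))` with `0 log 0 := 0`, and joint quantities come from
the tuple-valued variable over *observed* level combinations
(`joint_variable()`), so that `H(X,Y) = H(joint_variable(X,Y))` by
construction. MI, conditional MI and interaction information are derived
through the standard identities, which the test suite checks to 1e-12
against direct summation over explicit joint probability tables.

Two choices here are genuinely open and fixed as follows:

* **Discretization.** Continuous columns (at least 21 distinct values, the
  `continuity_threshold`) are cut at equal-frequency boundaries into
  `n_bins = 5` bins. Equal-frequency binning with about five bins is the
  common default in the MI-filter literature: it keeps every cell populated
  (stabilizing the plug-in estimate) and adapts to skewed marginals.
  Boundaries are taken from quantiles of the *distinct* values, so identical
  inputs can never straddle a boundary and the mapping is deterministic.
  Kernel-density, k-NN and bias-corrected MI estimators are deliberately out
  of scope.
* **Interaction information sign.** Conventions differ across the
  literature; we define `I(X;Y;Z) = I(X;Y) - I(X;Y|Z)`, so redundancy is
  positive and synergy negative (the XOR triple scores exactly -1 bit).
  The MRI criterion is the only consumer; under the opposite convention its
  correction term would flip sign.

All measures take a `base` argument (default 2, bits). Because every
selection criterion and the flow objective scale uniformly with the unit of
information, selections are invariant to the base — a property the tests
exercise rather than assume.

## The MI transfer network

From a dataset with n encoded features, `build_network()` computes

* the supply vector `b`, with `b[i] = I(f_i; C)`: the class information
  injected at feature node i;
* the capacity matrix `U`, with `U[i, j] = I(f_i; f_j)`: the most
  information an arc between two feature nodes can carry (symmetric, zero
  diagonal).

Two extra nodes complete the network: a sink T that collects delivered class
information, and a dummy node D that absorbs whatever supply is not
delivered, so that flow balance can hold at every feature node. The
"infinite" capacity of the arcs into T and D is represented by the finite
`big_M = sum(b)`: no feasible flow into the sink can exceed the total
supply, so the substitution is capacity-equivalent while keeping every
solver coefficient finite.

## The selection MILP

`build_model()` assembles, and `solve_model()` optimizes, the following
model over continuous arc flows `x` and binary indicators `y` (selected) and
`v` (terminal):

```
maximize   sum_i x[i,T]
subject to sum(y) = P                          (C1)
           sum(v) = 1,  v <= y                 (C2, C3)
           sum_j x[i,j] + x[i,D] + x[i,T]
             - sum_j x[j,i] = b[i]   for all i (C4)
           x[i,j] <= U[i,j] * y[i]
           x[i,j] <= U[i,j] * y[j]             (C5)
           x[i,T] <= big_M * v[i]              (C6)
           x[i,T] <= k[i]                      (C7)
```

Exactly P features are selected, and exactly one of them — the *terminal* —
may transmit into the sink (C2, C3, C6). Restricting the sink to a single
entry point is what makes the model a selector rather than a top-P-by-supply
ranking: the other selected features must route their class information
*through the terminal*, and an arc can only carry as much as the MI between
its endpoints, so the objective rewards subsets that are individually
relevant and mutually able to concentrate their information.

Two modelling details deserve comment because the formulation leaves them
implicit:

* **Coupling flows to the selection.** Without (C5) and (C3) the binary
  variables would not influence the flow problem at all. We gate every
  feature–feature arc by *both* endpoints' selection indicators and the sink
  arc by the terminal indicator; unselected supply drains to D. This is the
  minimal linear completion consistent with the two-layer reading of the
  network (selected non-terminal features feed the terminal, which alone
  feeds T), and the exhaustive oracle implements identical semantics, so the
  equivalence tests pin the interpretation down rather than assuming it.
* **Relays.** Flow balance naturally allows information to hop through
  intermediate selected features. Forbidding relays would need additional
  constraints with no basis in the model; we allow them, in both the solver
  and the oracle.

A redundant printed variant of the sink capacity (an ungated
`x[.,T] <= E` next to the gated form) is vacuous once E is any constant at
least `big_M` and is not materialized.

### Per-terminal bounds

(C7) uses the precomputed bound

```
k[i] = min( b[i] + top(P-1) of U[ ,i],  b[i] + top(P-1) of b[-i] )
```

— with terminal i, at most P-1 companions exist, everything entering the
sink beyond i's own supply must cross arcs into i, and no flow exceeds total
selected supply. The companion candidates are taken over *all* other
features, a precomputable superset relaxation of the unknowable unselected
set; supersets can only raise the maxima, so validity is preserved. The
tests verify `k[i]` dominates the true best per-terminal flow on every
enumerable instance, that `k` is monotone in P, and that it scales linearly
with the information unit.

### Solving: branch-and-bound on max-flow relaxations

No external MILP solver is required. The key structural fact is that once
the binaries (subset S, terminal t) are fixed, the model *is* a maximum-flow
problem: super-source to each selected node with capacity `b`, pairwise arcs
with capacity `U`, and a single capped arc from the terminal to the sink.
`solve_model()` therefore runs a best-first branch-and-bound over the
binaries. Each node of the search tree fixes the terminal and partitions
features into included / excluded / undecided, and is bounded by the
cheapest of three admissible relaxations: (i) the terminal's supply plus the
largest P-1 attainable direct capacities into it, (ii) the largest
attainable total selected supply, and (iii) the max-flow value over all
non-excluded features (cardinality-relaxed). Leaves are evaluated exactly.
The search stops when the best open bound is within the configured
`mip_gap` of the incumbent — the same relative-gap termination contract
commercial branch-and-bound solvers expose — and reports the achieved gap
and a status (`optimal`, `gap_reached`, `time_limit`). The default
`mip_gap` of 0.05 mirrors the tolerance at which the method is typically
run in practice; verification tests use gap 0.

Two independent flow routes are maintained on purpose: the solver's
relaxations use `igraph::max_flow`, while `exhaustive_oracle()` — which
enumerates every P-subset and terminal — uses a self-contained
Edmonds–Karp augmenting-path implementation. Their agreement on every
random instance with n ≤ 8 is one of the package's acceptance properties,
not a tautology.

Ties among optimal subsets: the solver returns its incumbent; the oracle
breaks ties toward the lexicographically smallest subset, then the smallest
terminal index. Equivalence tests compare objectives, never subsets.

### Degenerate inputs

A network with all-zero supplies has optimum 0 (any subset); `big_M` falls
back to 1 so capacities stay meaningful. Constant features carry zero
supply and zero capacity, and are flagged with a warning by the greedy
engine. Pruning uses an absolute tolerance of 1e-12 on bound comparisons;
an optimum can in principle be discarded by that margin, far inside the
1e-6 equivalence tolerance used for verification.

## The greedy family

`greedy_select()` implements the shared template — at each step add the
unselected f maximizing `I(C;f) - beta * sum_{fi in SEL} g(f, fi, C)` —
with the seven classical criteria as (beta, g) pairs (see
`?greedy_criterion` for the table). Points worth noting:

* The CIFE and IGFS g-functions are implemented in their joint-variable
  forms `I(f_i; C,f)` and `I(f; C,f_i)` as the summarized-algorithm
  literature tabulates them, even though some original papers write
  algebraically different variants; the table is treated as the contract.
* `1/|SEL|`-type beta rules are undefined at the first pick; the empty
  penalty sum makes the first pick relevance-only for every criterion,
  which the tests assert.
* MIFS-U divides by H(f_i); for a constant selected feature the whole term
  is defined as 0 (such a feature carries no information at all), never a
  division failure.
* Ties break toward the smallest feature index, making runs fully
  deterministic, and greedy runs are prefix-consistent: the first j picks
  of a length-m run equal the length-j run.

Scoring every candidate at every step costs exactly
`(2n - m + 1) m / 2` criterion evaluations (`evaluation_count()`); the
engine counts its evaluations and the tests check the identity for every
n ≤ 30.

## Synthetic data: what it emulates and what it does not

`generate_planted_dataset()` draws balanced classes and three feature
blocks: *informative* features, class-conditional Gaussians with adjacent
class means `class_signal` within-class standard deviations apart;
*redundant* features, noisy copies of informative parents (perturbation
standard deviation `redundancy_noise`); and *noise* features independent of
the class. Defaults — 5 informative, 5 redundant, 40 noise features, 500
observations, 2 classes, `class_signal = 2`, `redundancy_noise = 0.5` —
describe a strongly-but-not-separably informative signal buried among an
order of magnitude more irrelevant columns, with near-collinear duplicates
(a redundant copy at noise 0.5 retains roughly 80% of its parent's
variance), which is the regime filter methods are meant for. All
randomness flows through the spec's single seed, and the generator restores
the caller's RNG state.

These fixtures emulate relevance, redundancy and irrelevance — the factors
the selection criteria trade off — and both observations-to-features
regimes are reachable through the spec. They do *not* emulate heavy-tailed
or multimodal marginals, label noise, feature interactions without marginal
effects (pure XOR-type signals), or missingness. Passing the recovery tests
therefore demonstrates correct mechanics and sensible behaviour under the
planted model, not performance claims on any particular real dataset.

## Benchmark harness

`run_grid()` reproduces the standard protocol shape: each method selects
subsets over a grid of P, and every subset is scored by four off-the-shelf
classifier families (nearest neighbour, naive Bayes, linear SVM, linear
discriminant analysis; library defaults) so that no single model's bias
decides the comparison. The validation scheme is stratified 5-fold
cross-validation under a fixed seed — chosen because it is standard and
deterministic; the per-dataset accuracies are protocol-dependent and are
reported for comparison between methods, not as reproductions of any
published figure. `rank_methods()` ranks methods within each
(P, classifier) cell, ties sharing the better rank.

## Problem sizes used for verification

Exhaustive enumeration is only meaningful where it is exact, so oracle
equivalence, bound validity and the gap contract are verified on random
networks with n in 4–8 and P in 1–4 (50 instances in the test suite).
Planted-recovery runs use the default fixture (50 features, 500 rows) at
P = 5 and a 5% gap over ten seeds; the information-identity and
evaluation-count properties run on 100 random tables and all n ≤ 30
respectively. These sizes were chosen so the full suite exercises every
contract in well under a minute per module.

## Known limitations

* The flow objective values subsets whose members are mutually informative
  *about each other* as conduits to the terminal; a near-duplicate of a
  strong feature offers a high-capacity arc and can be co-selected (on the
  default fixture the optimum typically includes one redundant copy among
  four informative features). This is a property of the model itself, and
  distinguishes it from criteria that penalize pairwise redundancy
  explicitly.
* Branch-and-bound cost grows with n and with how flat the landscape is;
  the per-terminal bounds prune strongly when supplies are heterogeneous
  (the planted regime) but proven optimality (gap 0) on hundreds of
  features is not the intended use — that is what the gap tolerance is for.
* The plug-in MI estimator is biased upward on small samples; with very
  many levels and few rows, supplies of irrelevant features inflate. The
  permutation-null test in the suite bounds this effect on the default
  fixture but users with tiny n_obs should bin more coarsely.
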