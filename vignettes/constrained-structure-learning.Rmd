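---
title: "Exact structure learning with edge and path prior constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact structure learning with edge and path prior constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priordp)
```

## The problem

Score-based structure learning for a discrete Bayesian network seeks the DAG
$G$ maximising a decomposable score $\mathrm{Score}(G) = \sum_i
\mathrm{Score}(X_i, \mathrm{Pa}(X_i))$ over $n$ variables. Dynamic
programming over the *order graph* — the Hasse diagram of variable subsets —
finds the exact optimum in $O(2^n)$ subset evaluations: the best network
over a subset $U$ extends the best network over some $U \setminus \{X\}$ by
adding $X$ as a leaf with its best parent set drawn from $U \setminus \{X\}$,

$$\max \mathrm{Score}(V) = \max_{X \in V}\left[\max \mathrm{Score}(V
\setminus X) + \max_{\mathrm{Pa}(X) \subseteq V \setminus X}
\mathrm{Score}(X, \mathrm{Pa}(X))\right].$$

At small sample sizes the data alone rarely identify the structure. This
package integrates *deterministic prior knowledge* into the search itself:

* **edge constraints** — $X \to Y$ must (or must not) be a direct parent;
* **path constraints** — $X \Rightarrow Y$: $X$ must (or must not) be an
  ancestor of $Y$.

Required relations do double duty: they prune the order graph before search
(shrinking the planning space) and they restrict best-parent-set queries, so
every structure the search can return satisfies the prior.

## Scoring and the parent bound

The local score is natural-log BIC,
$\sum_{jk} N_{jk}\ln(N_{jk}/N_j) - \tfrac{\ln N}{2}\,q\,(r-1)$,
with $q$ the full product of parent cardinalities (unobserved parent
configurations add nothing to the likelihood but are still penalised — the
deterministic convention) and $0\ln 0 \equiv 0$. In a BIC-optimal network no
node can afford more than a few parents at small $N$; the bound used is
$\mathrm{nmp} = \lceil \log_2(N/\log_2 N)\rceil$, floored at 1 (3 parents at
$N = 20$, 7 at $N = 1000$), overridable via `max_parents` arguments for
users who know their domain is denser. Only families within the bound are
scored and searched, which is what makes the sparse parent graphs small.

## Order-graph pruning

Required edges and required paths both assert ancestry, so they pool into
one *constraint graph* $G_C$ over the constrained variables. A subset $U$
must leave the order graph iff some required ancestry $X \Rightarrow Y$
(inferable by transitive closure of the required relations) has $Y \in U$
but $X \notin U$ — every completion of such a $U$ would place $X$ after its
required descendant. Rather than filtering all $2^n$ subsets, the search
*constructs* only admissible subsets: from $U$ it may append an
unconstrained variable, or a constrained variable that is a root of $G_C$
restricted to the not-yet-placed constrained variables. The suite verifies,
over random constraint sets, that the subsets this expansion reaches are
exactly those passing the deletion predicate. Forbidden relations never
prune the order graph — forbidding ancestry constrains structure, not
placement order — and are enforced purely at query time.

The planning-space count (non-empty admitted subsets) factorises as
`(ancestor-closed subsets of the constrained block) * 2^(free variables)
- 1`, which `count_order_graph_entries()` evaluates analytically; with no
required constraints it is $2^n - 1$ (262,143 at $n = 18$).

## Sparse parent graphs and bitvector queries

Per child, candidate parent sets are stored sorted by score (ties broken by
smaller subset mask, fixed at sort time for cross-platform determinism),
with one membership bit array per variable. Three modes:

* **unconstrained** — dominance pruning stores a set only if it strictly
  beats every proper subset's best score; the top stored subset of any
  candidate superset then attains the unconstrained optimum.
* **edge-pruned** — sets containing a forbidden parent are never stored, and
  the dominance recursion never removes a required parent, so the chains of
  comparisons the query needs survive pruning.
* **full** — a child that is the tail of *any* path constraint stores every
  family up to the parent bound, unpruned, because which sets are admissible
  depends on descendant relations in the substructure current at query time
  and cannot be decided at construction. ("Tail" covers forbidden paths as
  well as required ones: a forbidden-ancestor filter over a dominance-pruned
  table could strand the query on a set whose dominated substitutes were
  discarded.) The empty set is always a candidate — otherwise root nodes
  would be impossible.

An edge query ANDs the membership rows of required parents and the
complemented rows of out-of-candidate and forbidden variables; the first
surviving entry is the answer. A path query additionally builds, per
required ancestor $X$, an OR-accumulated array over the rows of
$\{X\} \cup \mathrm{des}(X)$ (descendants taken in the best substructure
over the placed variables, reconstructed on demand from DP backpointers) —
initialised to all-zero so the OR accumulates from nothing — and ANDs it in;
forbidden ancestors contribute complemented rows of their closure. An empty
validity array is a recoverable signal, not an error: the DP skips that
extension, since under forbidden constraints a leaf extension can be
genuinely inadmissible.

## Numerical and engineering choices

* Subset masks are machine integers (bit $i$ = variable with 0-based index
  $i$); the implementation supports $n \le 30$, and memory bounds practical
  use near $n \le 20$ ($2^n$ order-graph slots).
* All order-graph entries (score, last-added variable, its parent set) are
  kept in flat preallocated vectors rather than a two-layer rolling table:
  at this scale the flat table is smaller than a hash scheme, and
  path-constrained queries need to reconstruct arbitrary intermediate
  substructures anyway.
* Ties between two extension routes into the same subset keep the smaller
  (last-added, parent-mask) pair, making learned structures deterministic.
* Variable indexing is 0-based internally; all I/O refers to variables by
  name. CPT rows index parent configurations in mixed-radix order with the
  lowest parent index most significant — one fixed convention shared by
  fixture files, sampling and scoring.

## What the synthetic generator emulates

`random_network()` draws a DAG edge-wise in a fixed topological order
(`edge_prob = 0.3` by default, giving sparse graphs comparable to the
benchmark networks) and CPT rows from a symmetric Dirichlet with
`dirichlet_alpha = 0.5`. The sub-uniform concentration deliberately favours
skewed conditionals — the classic benchmarks (e.g. the chest-clinic
network's near-deterministic CPTs) are skewed, and skew is what makes
structure identifiable at moderate sample sizes. `forward_sample()` then
draws rows ancestrally. What this does *not* emulate: real measurement
noise, missing data, latent confounding, or selection effects — a passing
recovery test shows BIC consistency on faithful discrete data, not
robustness to misspecification. The embedded protein-signalling fixture
keeps the published 11-node consensus structure but carries *synthetic*
CPTs (seed-pinned Dirichlet draws), so runs against it exercise the
machinery rather than reproduce published parameter values; the chest-clinic
fixture uses its canonical published CPTs.

`sample_constraints_from_truth()` turns a fraction of the true edges (or of
the true ancestral closure) into required constraints, which is how the
evaluation harness emulates an expert who knows part of the structure.

## Validation strategy and problem sizes

Everything search-related is validated against independent brute force at
desk scale: an exhaustive enumeration oracle over all labelled DAGs
($n \le 5$; 25/543/29,281 DAGs for $n = 3,4,5$, cross-checked against the
labelled-DAG counting recurrence), linear-scan query oracles, a
path-enumeration closure oracle, and permutation search for acyclicity. The
test suite runs 50 random score landscapes per $n \in \{3,4,5\}$ for each
constraint regime, 100 random constraint sets for the pruning equivalence,
and 20 six-node recovery replicates at $N = 5000$; these sizes were chosen
so the whole suite completes in well under a minute while still exercising
every code path.

## Known limitations

* **Path-constrained optimality is not guaranteed.** When a new leaf's
  admissible parent sets are judged against descendant relations, the DP
  consults the single best-scoring substructure retained for the placed
  set. A completion that is only admissible under a *lower-scoring*
  substructure is invisible, so the returned network can score below the
  true constrained optimum (the oracle-equivalence suite measures this on
  random instances and logs each counterexample; returned networks always
  satisfy the constraints and never out-score the oracle). Edge-constrained
  and unconstrained learning are exactly optimal.
* Constrained and unconstrained optima are compared on the identical score
  cache, where dominance (constrained $\le$ unconstrained) holds by
  construction; score comparisons across different caches are meaningless.
* No BDeu/K2/AIC scores, no missing-data handling, no continuous or latent
  variables, and no Markov-equivalence-aware distance (SHD counts a
  reversal as 1).

## A complete run

```{r example, eval = FALSE}
bn <- benchmark_fixture("asia")
d <- forward_sample(bn, 20, seed = 1)

# unconstrained learning at N = 20 finds little
fit0 <- bn_learn(d)

# with the seven listed ancestor pairs as required paths
cs <- fixture_path_constraints("asia")
fit1 <- bn_learn(d, cs)
check_constraint_satisfaction(fit1$dag, cs)$ok

glance(fit1)
tidy(fit1)
```
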