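---
title: "Quartet and triplet methods for cell lineage trees under error and missingness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quartet and triplet methods for cell lineage trees under error and missingness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quartetlineage)
```

## The generative model

Tumors evolve clonally, so the history of a set of sequenced cells is a
*rooted cell lineage tree* whose root is the healthy cell. Single-cell
mutation data are modeled here in two stages.

**Infinite sites (IS).** The model tree `sigma` carries a probability
`p(e)` on every edge, with probabilities summing to 1. Each of the `k`
mutations independently picks one edge and marks with state 1 exactly the
cells below that edge; everything else is 0. A mutation is therefore a
bipartition (unrooted view) or a clade (rooted view) of the cell set.
Internal edges must have positive probability (an internal edge that can
never mutate is contracted away); a *terminal* edge may have probability
exactly 0, in which case the attached leaf is a sampled cell identical to
its internal ancestor. We call such edges and leaves *fake*, following the
convention that sampled ancestral cells hang off the tree on zero-mass
edges.

**Unbiased error and missingness (UEM).** Each matrix entry is then passed
independently through a three-parameter channel: a true 0 is read as 1
with probability `alpha` (false positive), a true 1 as 0 with `beta`
(false negative), and any entry is masked as `?` with `gamma`. All three
lie in `[0, 1)`. `error_model()` constructs the triple and flags the
degenerate line `alpha + beta = 1`, on which observed quartet frequencies
carry no topological signal at all.

In `quartetlineage`, the tree is a `lineage_tree` (an `ape::phylo` whose
branch-length slot stores the mutation probabilities), the channel is an
`error_model`, and `simulate_mutation_matrix()` draws the observed matrix
`D` (and optionally the ground truth `G`) under a fixed pseudo-random
stream order so a seed pins the output bit-for-bit.

## Sub-models and restriction

Every analytic statement reduces to trees on three or four cells via
*restriction*: delete the other leaves, suppress degree-2 vertices, and
add the probabilities of merged edges. Restriction must remain a valid
sub-model — the pattern probabilities on the retained cells may not
change. Two bookkeeping terms make this exact in `restrict_tree()`:

* edges above the MRCA of the retained set would mark *every* retained
  cell, so their mass moves to a root-stem edge (`root.edge`);
* edges with no retained descendant produce the all-zero pattern, and
  their mass is kept as `null.prob`.

Edge mass + stem + null always totals 1, and
`is_pattern_distribution()` computed on the original tree equals the same
computation on the restriction (the test suite checks this identity on
random trees).

## Why quartets are safe and triplets are not

On four cells there are 16 patterns; 1100/0011 support the quartet
`AB|CD`, 1010/0101 support `AC|BD`, 1001/0110 support `AD|BC`.
`quartet_distribution_uem()` evaluates the closed-form probabilities of
the three quartets under the channel: a background term `f` shared by all
three topologies, a retention coefficient
`(1-alpha)^2 (1-beta)^2 + alpha^2 beta^2` on the displayed topology, and
a leakage coefficient `2 alpha beta (1-alpha)(1-beta)` on the other two.
Only fully observed patterns are informative, so missingness contributes a
factor `(1-gamma)^4`. Pairwise differences collapse to

```
P(q_i) - P(q_j) = (1 - (alpha + beta))^2 (1 - gamma)^4 (P_IS(q_i) - P_IS(q_j))
```

which is positive whenever the IS difference is and `alpha + beta != 1`:
**no quartet alternative can overtake the displayed quartet**. At the
harshest parameter corner used in published tumor simulations
(`alpha = 0.001`, `beta = 0.2`, `gamma = 0.05`) the retention factor is
`0.799^2 * 0.95^4 = 0.52`: half the IS signal survives the channel.

Triplets read the root: a pattern with two derived cells and one
ancestral cell supports the triplet whose outgroup is the ancestral cell.
`triplet_distribution_uem()` evaluates the analogous closed forms, but
the pairwise difference keeps an extra term

```
alpha (1 - (alpha+beta)) (P_IS(x_j) - P_IS(x_i))
```

in the *singleton* pattern probabilities `x`. With `alpha > 0`, an
alternative triplet `t_j` becomes **anomalous** — strictly more probable
than the displayed triplet — exactly when

```
(alpha / (1 - beta)) (P_IS(x_i) - P_IS(x_j)) > P_IS(t_i) - P_IS(t_j)
```

(`triplet_anomaly_condition()`; missingness cancels). At the corner above
the coefficient is `1/800`, so the singleton-pattern difference must be
800 times the triplet difference. That sounds extreme, but restriction
makes it easy: `build_augmented_lineage_fixture(m = 1000)` constructs a
lineage tree in which a long chain of 1008 clones separates a small
cherry (cells 1 and 4) from cell 10. Restricted to `{1, 4, 10}` the
sub-model has `P(x_10) = 1009/1012` versus a displayed-triplet mass of
only `1/1012`, and `find_anomalies()` flags both alternatives:

```{r fixture}
fx <- build_augmented_lineage_fixture(1000)
em <- error_model(ratio(1, 1000), ratio(1, 5))
find_anomalies(fx, em, mode = "triplet", subsets = list(c("1", "4", "10")))
```

The calculators run in exact rational arithmetic (the `ratio` class) when
the tree carries integer numerators and the error model is built from
`ratio()` values, so statements like "strictly greater" are decided
exactly rather than at floating-point tolerance.

## Estimation: maximum quartet/triplet support

Each informative mutation is an unrooted tree with at most one internal
branch, so quartet supertree machinery applies directly. The *quartet
support* of a candidate tree `B` is

```
QS_D(B) = sum over 4-subsets S of w_D(B|_S)
```

where `w_D(q)` counts the mutations implying quartet `q`
(`quartet_weights()` / `quartet_support()`). Maximising `QS_D` over
binary trees is the Maximum Quartet Support Supertree (MQSS) problem;
`mqss_exhaustive()` solves it exactly for up to 8 cells,
`mqss_constrained()` solves it within a bipartition constraint space
built from the mutations themselves (`build_constraint_space()`), and
`mqss_nni()` is a seeded nearest-neighbor-interchange hill climber for
larger cell sets. `mtss_exhaustive()` is the rooted, triplet analogue.

Because model trees are highly unresolved, error is scored as the number
of **false negative branches** (`tree_error()`): internal bipartitions of
the model tree missing from the estimate. FN error is 0 exactly when the
estimate *refines* the model tree, which is the best a binary-output
method can do against a polytomy. The no-anomalous-quartets property
implies that an optimal MQSS solution is a consistent estimator of the
unrooted model tree in this metric for any `alpha + beta != 1`; the
triplet analogue needs `alpha = 0`, and the fixture above shows why: with
false positives, the most-supported triplet at infinite data can be a
wrong one, while the quartets around the same cells stay sound.

## Choices a user can tune, and the defaults

* **Edge probabilities** default to uniform over non-fake edges in every
  constructed fixture — the standard "mutations occur on all non-fake
  edges with equal probability" convention. `random_lineage_tree()`
  instead draws symmetric-Dirichlet(1) probabilities, for scans where
  heterogeneous edge masses are the point.
* **Error parameters**: no defaults; the corner `(0.001, 0.2, 0.05)` is
  used throughout the examples because it is the harshest setting in the
  published simulation studies this model family comes from.
* **Exact versus floating arithmetic**: exact is automatic when both
  inputs carry exact values; numerators and denominators are doubles
  guarded at `2^53`, which covers the worked fixtures (denominators near
  `10^15` after reduction). Randomized scans use floating point with a
  `1e-12` strict-inequality margin in anomaly checks.
* **Tie-breaking**: all solvers break score ties toward the
  lexicographically smallest canonical Newick string and report the
  number of co-optima, so reruns are reproducible.
* **Missing-data completion for the constraint space**: missing cells
  join the zero (ancestral) side by default (`completion = "zero"`), or
  the column can be dropped (`"drop"`). This is a documented choice, not
  a model-mandated rule; it only affects which bipartitions enter the
  search space, never the score of a tree.
* **Caps**: exhaustive search refuses more than 8 cells (10395 unrooted
  topologies) unless the cap is raised; full anomaly scans refuse more
  than `1e6` subsets unless an explicit subset list is passed.

## What the simulator does and does not emulate

`simulate_mutation_matrix()` reproduces the generative model exactly:
i.i.d. mutations, per-entry independent unbiased errors and missingness,
fake leaves observed through the same channel as real ones. It does
**not** emulate doublets, copy-number aberrations, cell- or site-biased
error rates, or mutation-rate variation along the genome — all named
extensions of this model family. Passing tests therefore certify the
mathematics of the IS+UEM analysis and the correctness of the estimation
code, not robustness of the method on real tumor data, where biased
errors and CNAs are known additional hazards.

## Problem sizes in the shipped experiments

The consistency experiments run exhaustive MQSS on 6-leaf model trees
(binary, and with one polytomy) at `k = 2000` mutations and 20
replicates, where recovery is expected in at least 18 of 20 seeds; the
quartet-versus-triplet fragility comparison samples the four cells
`{0, 1, 4, 10}` around the fixture's anomalous triplet and runs both
exhaustive solvers at `k = 300000` for three replicates. These sizes were
chosen so that every experiment is exact (no heuristic search) while the
law-of-large-numbers effects the theory predicts are already visible.

## Known limitations

* Exhaustive and constrained solvers enumerate topologies, so they stop
  at small cell counts; the NNI climber has no optimality guarantee.
* The constrained solver uses filtered enumeration rather than a clade
  dynamic program, so it shares the exhaustive cap instead of scaling the
  way production supertree heuristics do.
* Exact arithmetic overflows beyond `2^53` numerators/denominators
  (roughly: channels whose parameter denominators multiply past `10^15`
  on four cells); the calculators then have to be run in floating point.
* Weight tables are dense over subsets, which is comfortable to ~30
  cells but not beyond.
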