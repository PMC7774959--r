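---
title: "Locating solitary-bee nesting aids in orchards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating solitary-bee nesting aids in orchards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmiaplace)
```

## The problem

Cavity-nesting solitary bees such as *Osmia cornuta* are effective orchard
pollinators, but unlike honey bees they forage only a short distance from
their nest. A grower installing artificial nesting aids therefore faces a
facility-location problem: every tree must lie within the bees' foraging
range of some aid, aids cost money and maintenance, and shorter flights
mean denser visitation. osmiaplace formalizes this as a lexicographic
two-stage program over the trees of the orchard (an aid can only be
mounted on, or under, a tree):

* **Stage 1 (set covering).** Minimize the number of aids $p$ such that
  every tree $j$ has $\min_i d_{ij} \le K$, where $d_{ij}$ is the
  Euclidean distance from candidate site $i$ to tree $j$ and $K$ is the
  foraging range.
* **Stage 2 (capped $p$-median).** With $p^{*}$ fixed at the stage-1
  optimum, choose the $p^{*}$ sites minimizing
  $\sum_j \min_i d_{ij}$, still subject to the $K$ cap.

The priorities are strict: no trade-off between aid count and flight
distance is ever made; stage 2 optimizes only within the set of stage-1
optima.

The classical binary formulation of this problem assigns one variable per
candidate site plus one per (site, tree) pair, i.e. $n^2 + n$ variables —
`binary_model_size(2184)` is `r format(binary_model_size(2184), big.mark = ",")`
for a one-hectare orchard, far beyond exact solvers. The package instead
encodes a candidate solution as a short vector of tree indices (the
reduced encoding has only $2p$ variables) and searches it with
differential evolution, validating against exact enumeration on small
instances.

## Coverage semantics

Three numerical choices deserve an explicit statement.

* **Distances are true Euclidean distances.** The coverage constraint is
  $\sqrt{(a_j-a_{x_i})^2+(b_j-b_{x_i})^2} \le K$ with $K$ in meters.
  Formulations of this model are sometimes written with the squared
  radicand compared directly against the range; since $K = 50$ is a
  length and the distance objective uses the square root, the package
  consistently uses the rooted form everywhere. Internally fitness works
  on squared distances and compares against $K^2$, which is exact,
  including the boundary case (coverage is boundary-inclusive: a tree at
  exactly $K$ meters is covered).
* **Duplicate aid positions collapse.** An individual's genes may name
  the same tree several times; the placement then contains that aid
  once. The stage-1 objective is the *effective* aid count — the number
  of distinct positions serving at least one tree under nearest
  assignment. This is what lets a 10-gene individual represent a 3-aid
  or 4-aid solution, and it is the only reading under which the aid
  count can fall below the gene count at all.
* **Ties break low.** When two aids are equidistant from a tree
  (including the exact-duplicate case), the aid in the lowest vector
  slot serves it. All reported results are therefore deterministic
  functions of the placement.

Infeasibility is handled by an additive penalty: each uncovered tree adds
`penalty` (default $10^6$ m) to the fitness. The default exceeds $n$
times the diameter of every shipped layout, so any feasible placement
scores strictly below any infeasible one and the two stages cannot trade
coverage for distance.

## The differential-evolution scheme

The solver is classic rand/1/bin over integer genes: for each target
$x_i$, a mutant $v = x_{r_1} + f\,(x_{r_2} - x_{r_3})$ is built from
three distinct other members, mixed gene-wise with the target at
crossover rate `cr` (one mutant gene guaranteed), repaired by rounding
to an integer and clamping to $[lb, ub]$, and kept only if its fitness
is no worse than the target's. Rounding is what keeps aids on trees;
gene value 0 (the conventional lower bound) maps to tree 1 at
evaluation. The only stopping rule is the generation count $g$; the best
fitness of every generation is recorded in a history vector, which
greedy selection makes non-increasing.

Control parameter defaults, used for the one-hectare case studies:

| parameter | default | meaning |
|---|---|---|
| `dim` | 10 (stage 1), $p^{*}$ (stage 2) | genes per individual = max aids |
| `np`  | 100 | population size |
| `g`   | 1000 | generations (the stopping criterion) |
| `cr`  | 0.2 | crossover constant |
| `f`   | 0.9 / 0.1 | mutation constant, stage 1 / stage 2 |
| `lb`, `ub` | 0, $n$ | gene bounds |

The stage-1 mutation constant is large because the search must both
reach feasibility and collapse genes onto few positions; stage 2 uses a
small constant because it refines around an already-known aid count.
Stage 2 starts from a fresh uniform population by default —
`warm_start = TRUE` seeds it with the stage-1 placement instead, but the
low mutation constant alone reproduces the intended "search near the
stage-1 solution" behavior, so warm starting is off by default.

Two behaviors of this landscape are worth knowing. First, collapsing to
very few aids is the slow part of stage 1: a population that has
converged to a two-position cover can only reach a one-position cover if
the single covering tree's index is generated by mutation while gene
diversity remains, so short runs systematically overestimate $p^{*}$ on
easy instances. The full $g = 1000$ budget is what makes the solver
reliable there; results below quote the budgets used. Second, the
strategy is deliberately the textbook rand/1/bin; popular library
defaults use local-to-best variants, which would change seeds-to-answer
but not the contract (the exact oracle, not a particular trajectory, is
the reference).

## Exact oracle

`exact_min_aids()` and `exact_p_median_capped()` enumerate site subsets
(in lexicographic order, which doubles as the deterministic tie-break)
and are provably optimal; a `size_limit` (default 30 trees) refuses
instances whose enumeration would be unreasonable. No
integer-programming backend is configured; enumeration is the oracle of
record. Monotonicity properties — the optimum aid count is non-increasing
in $K$, the optimal total distance non-increasing in $p$ — are asserted
in the test suite.

## Orchard generators

`generate_grid()` produces the commercial planting pattern: trees every
1.2 m along a row, rows every 4 m, over a union of axis-aligned
rectangles (boundary-inclusive with a $10^{-9}$ m tolerance, origin at
(0, 0) — under which the published square-orchard aid coordinates are
exact lattice multiples). Ids are row-major. The 100 m × 100 m square
holds 84 × 26 = 2,184 trees.

`orchard_shape("L")` and `orchard_shape("X")` are the package's own
one-hectare rectangle unions (a 60 × 80 m block with a thin 325 × 16 m
arm; a 40 m wide bar crossed by a 20 m tall bar). They are synthetic
stand-ins: published L- and X-shaped case-study orchards with 2,154 and
2,146 trees exist, but their rectangle decompositions are not printed,
only their supplementary coordinate files define them. Any tree list can
be supplied via `read_treeset()` instead.

`generate_random()` emulates an irregular orchard that still respects
the grower's minimum spacings: rows drawn with at least 4 m separation,
within-row positions with at least 1.2 m gaps, both by the
sorted-uniform-plus-gaps construction, so the spacing post-condition
holds by construction rather than by rejection. What it does *not*
emulate: clustered or thinned plantings, terrain, missing trees, or any
covariance between tree position and bloom — passing tests on these
fixtures says the optimizer works on spatially regular point sets, not
that 50 m is the right range for a given orchard.

## What the tests establish

The suite validates the solver three ways, at these problem sizes:

* **Oracle equivalence.** On 20 random instances with 8–15 trees and
  $1 \le p^{*} \le 3$, best-of-10-seeds DE (np = 100, g = 1000 for
  stage 1, g = 250 for stage 2) reproduces the enumeration optimum of
  both stages exactly, every final placement covers all trees at $K$,
  and every history vector is monotone.
* **Published square-orchard results.** The generated 2,184-tree grid,
  stage 1 at the case-study parameters (g reduced to 200, which does
  not change the optimum there), returns 4 aids for each of 10 seeds;
  the four published aid positions evaluate to a total flight distance
  of 42,740.96 m.
* **Component oracles.** Nearest assignment against a double-loop
  implementation (exact float agreement), effective counts against a
  direct used-slot marking, enumeration against an independent bitmask
  enumeration, grid generation against brute-force containment.

The published random-layout (1,000 trees), L- and X-shaped case results
depend on a supplementary coordinate file that is not redistributable
with the package; the corresponding check runs only when those
coordinates are installed under `inst/extdata/s1/`.

## Limitations

* The foraging range is a hard disk; real visitation declines with
  distance rather than stopping.
* All trees are weighted equally; no bloom intensity or cultivar
  compatibility weighting.
* The exact oracle is enumeration-only and does not scale past a few
  dozen trees; large-instance results carry a metaheuristic, not a
  proof.
* DE results are seed-dependent; headline runs are reported best-of-10
  seeds, and all seeds are logged.
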