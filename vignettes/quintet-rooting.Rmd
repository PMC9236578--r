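---
title: "Rooting species trees from quintet topology distributions: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rooting species trees from quintet topology distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quintetroot)
```

## The model

Gene trees evolving inside a species tree under the multi-species
coalescent (MSC) disagree with the species tree because lineages that enter
a short ancestral branch may fail to coalesce there (incomplete lineage
sorting, ILS).  The disagreement is informative: Allman, Degnan and Rhodes
(*J. Math. Biol.* 62:833–862, 2011; henceforth ADR) proved that the
distribution of the 15 *unrooted* gene-tree topologies on five taxa
identifies the *rooted* five-taxon species tree.  Concretely, for a rooted
quintet species tree the vector $(u_1,\dots,u_{15})$ of unrooted gene-tree
topology probabilities satisfies

* **invariants**: a partition of $\{1..15\}$ into equivalence classes whose
  members have equal probability for *every* assignment of branch lengths,
  and
* **inequalities**: strict dominance relations between classes,

and this structure depends only on the topological *shape* of the rooted
tree: caterpillar `((((a,b),c),d),e)`, balanced `(((a,b),c),(d,e))` or
pseudo-caterpillar `(((a,b),(d,e)),c)`.  Rooting therefore reduces to asking
which candidate rooting's structure the observed topology frequencies fit
best.  Only topologies enter: substitution rates, clock violations and
branch-length estimates are irrelevant by construction (`perturb_clock()`
provably cannot change the result, and a test asserts this).

## The cost function

For an empirical distribution $\hat u$ (gene-tree topology frequencies,
`quintet_frequencies()`) and a candidate rooted quintet $R$ with classes
$C_R$ and order pairs $c > c'$:

$$\mathrm{Cost}(R,\hat u) = \sum_{c\in C_R}\frac{1}{|c|}
\sum_{u_a,u_b\in c}|\hat u_a-\hat u_b|
\;+\; \sum_{c>c'}\frac{1}{|c'|}\sum_{a\in c,\,b\in c'}\max(0,\hat u_b-\hat u_a).$$

The cost is zero iff every within-class pair is equal and no dominance pair
is strictly reversed; it is compared across candidates, never tested for
equality, so no tolerance is applied inside the formula (the hinge sits at
exactly 0).

**Ordered pairs.** The within-class sum runs over *ordered* pairs, so each
$|\hat u_a - \hat u_b|$ enters twice (implementation weight $2/|c|$ per
unordered pair).  This is a deliberate reading of the double-sum notation,
fixed by an arithmetic checksum: the weighted number of penalty terms,
$\sum_c \frac{1}{|c|}|c|(|c|-1) + \sum_{c>c'}\frac{1}{|c'|}|c||c'|
= \sum_c(|c|-1) + \sum_{c>c'}|c|$, evaluates to 19/20/19 for the
caterpillar/balanced/pseudo-caterpillar shapes — the published
near-equality that motivates the normalization — whereas the unordered
reading gives 15/15/14.  Functionally, only the ordered reading reproduces
the documented behaviour of the unnormalized variants (below).

**Variants.** `quintet_cost(..., variant =)` supports: 1 — invariants only
(normalized); 2 — both penalties, all weights 1; 4 (default) — the full
normalized cost.  A third variant with an alternative normalization exists
in the literature but its exact weights are specified only in supplementary
material that was not available when this package was written; rather than
guess, variant 3 raises an informative error and is excluded from defaults.

**Category bias.** The number of distinct penalty terms differs by shape
(46/67/85), so unnormalized costs are systematically smaller for some
candidate shapes than others.  An acceptance test reproduces the
consequence at the cost-design experiment's ILS level (29% average
discordance; 500 random quintet model trees, 800 gene trees each): the
per-shape spread of mean rooting error is about 0.08 for the normalized
cost against about 0.22 (unnormalized) and 0.32 (invariants only).

## Table conventions and their provenance

The package enumerates unrooted quintet topologies canonically: a topology
is its two disjoint cherry pairs, ranked lexicographically (index 1..15,
taxa mapped to positions a..e by sorted label).  A rooted quintet is
(topology, root edge) with edges 1..5 pendant and 6..7 internal, id
$(t-1)\cdot 7 + e$.  The three base structures are hard-coded for the
reference trees above and pushed onto all 105 rooted quintets by the leaf
relabeling carrying the reference tree onto the target
(`adr_structure()`, `adr_structures()`, exportable with `adr_table()`).

The correspondence between the literature's $u_1..u_{15}$ and the canonical
indices, and the exact inequality pair sets, are not fully printed in the
primary sources available here; they were *derived* and then pinned by
checksums:

1. $u_1$ is the unrooted topology shared by the three reference trees
   ({ab},{de} cherries).
2. Equivalence classes must be unions of orbits of each reference tree's
   *parameter-free* automorphisms (the cherry swaps $(ab)$, $(de)$; the
   pseudo-caterpillar's $(ad)(be)$ swap exchanges two internal branch
   lengths and is **not** parameter-free, which is exactly why
   $\{u_2,u_3\}$ and $\{u_4,u_{13}\}$ remain distinct classes).  Combined
   with the three printed partitions this forces the bijection up to
   within-class swaps that provably leave all 105 derived structures
   unchanged.
3. The inequality pair sets must reproduce two independent printed
   checksums — 28/44/54 unweighted inequality terms and 19/20/19 weighted
   totals — and contain only relations valid for *all* branch lengths.
   For the caterpillar this still leaves a small family; two further
   constraints single out the implemented set
   ($u_1>u_2$; $u_3>u_2$; $u_3>\{u_4,u_{13}\}$; $u_3>\{u_6,u_9\}$;
   $u_2>\{u_5,u_{12}\}$; $\{u_4,u_{13}\}>\{u_5,u_{12}\}$;
   $\{u_6,u_9\}>\{u_5,u_{12}\}$; $\{u_5,u_{12}\}>\text{bottom}$):
   the relation $u_1>\{u_6,u_9\}$ fails in the coalescent limit with the
   two lower internal branches short and the upper one long (the balanced
   merger probability $1/9$ exceeds the caterpillar chain's $1/18$), and
   the set must leave no competing rooting at exactly zero cost under the
   exact distribution of any other rooted tree — without
   $u_3>\{u_4,u_{13}\}$, adjacent caterpillar rootings tie at cost 0
   against an exact balanced-tree distribution, contradicting
   identifiability.

A seed-pinned Monte-Carlo test re-verifies the whole construction: at
$10^5$ simulated gene trees per reference shape, within-class frequencies
pass pooled two-proportion z-tests (α = 10⁻⁴, Bonferroni) and every order
pair holds strictly; and the cost's argmin over all 105 rooted topologies
recovers each simulating tree.

## Trees with more than five taxa

Each of the $2n-3$ candidate rootings is scored as the sum over a subset
$Q^*$ of five-taxon sets of the cost of the candidate's induced rooted
quintet against that set's empirical distribution.  `mode = "all"` takes
every $\binom{n}{5}$ subset; per subset the distribution is tallied once
and the cost of each *distinct* induced rooted quintet (at most 7 of the
105) is computed once and cached — a test verifies cache-equals-naive.
Restriction of gene trees is implemented through pairwise topological leaf
distances and the four-point condition, vectorized over gene trees;
unresolved restrictions (polytomies) contribute to no count and are
logged, and gene trees missing any of the five taxa are excluded from both
numerator and denominator.  Subsets with no qualifying gene tree are
skipped and counted in the result.

`mode = "linear"` keeps the same contract with $O(n)$ subsets.  The
published linear encoding is defined in supplementary material unavailable
here, so the package ships a documented stand-in (strategy
"edge-spanning"): for each internal edge of the unrooted tree, one quintet
containing the nearest leaf inside each of the four subtrees the edge
separates plus the nearest remaining fifth leaf, with deterministic
label-order tie-breaks — at most $n-3$ subsets, each candidate root edge
visible to at least one of them.  A different published scheme can be added
behind the same interface without changing results contracts.

Ties in the final argmin (within $10^{-12}$) are broken towards the lowest
canonical edge id — edges are identified by their far-side leaf sets,
ordered by size then lexicographically, so results are reproducible across
runs and platforms — and flagged in the result.

## The simulator and what a green test establishes

`sim_gene_trees()` implements the standard MSC: one lineage per species at
each tip; within a species-tree branch of length $t$ coalescent units (CU)
holding $m$ lineages, the next merger arrives after an
$\mathrm{Exp}\binom{m}{2}$ wait and joins a uniform pair; survivors
coalesce above the root.  Pendant branch lengths cannot affect topology
probabilities.  Defaults used throughout the tests: pendant branches 1 CU;
interior branches as stated per experiment — 0.5 CU for the
identifiability checks (a moderately high ILS level), $U(0.3, 1.4)$ CU for
the cost-comparison experiment (calibrated once so that average
discordance matches that experiment's stated 29%), and $U(0.2, 1.0)$ CU
for the 10-taxon recovery experiment (average discordance 40–49%, inside
the stated 30–50% band).  One seeded generator per call, genes drawn
sequentially (R has no cheap splittable streams; sequential draws from one
seeded generator meet the reproducibility contract, and the
topology-index fast path consumes the identical stream — asserted by a
test).

What the generator does **not** emulate: sequence evolution and
maximum-likelihood gene-tree estimation.  Estimation error is approximated
by random NNI rearrangements (`perturb_nni()`), which is a topological
noise model, not a likelihood one.  A green suite therefore establishes
correctness of the combinatorics, the cost, and the rooting algorithm
under the MSC with *true* (or NNI-noised) gene trees; it does not certify
accuracy under realistic gene-tree estimation error, alignment error or
model misspecification.

## Numerical and design choices

* No thresholding inside the cost; normalization of the input distribution
  is the caller's job and is checked to $10^{-9}$.
* The empirical distribution's denominator counts only qualifying,
  binary-restricted gene trees.
* Degenerate regimes: at the uniform distribution every rooting costs 0
  (tie flagged); as ILS vanishes the distribution approaches a point mass
  and all rootings of the true unrooted topology approach cost 0 — the
  rooting signal lives in the *discordant* topology frequencies and is
  strongest at intermediate ILS.  Near-caterpillar trees with a short
  deepest internal branch are intrinsically hard: the only signal ordering
  the two rootings adjacent to the root is the small gap between two
  specific topology probabilities.
* `random_model_tree()` draws a uniform rooted topology with uniform
  interior branch lengths; it is a fixture generator, not a biological
  prior.

## Known limitations

* Statistical consistency of cost-based rooting is an open question; the
  exact-distribution argmin is unique (verified empirically over the 105
  topologies at the reference parameters), but finite-sample selection
  between near-tied rootings is noise-driven.
* Variant 3 of the cost and the published linear-encoding subset scheme
  are not reproduced (unavailable sources); the stand-ins are labelled.
* The all-subsets mode costs $\Theta(k n^2 + \binom{n}{5}(k + n))$ time in
  this implementation and is practical to a few dozen taxa; the linear
  mode extends further but is less accurate.
* Gene trees are assumed correctly labelled and single-copy; paralogy,
  duplication/loss and horizontal transfer are outside the model.
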