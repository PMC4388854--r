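---
title: "Canonical forms for weighted phylogenetic networks: model, algorithms and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical forms for weighted phylogenetic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocanon)
```

## The model

A *weighted rooted phylogenetic network* on a taxon set X is a rooted DAG
whose outdegree-0 nodes are bijectively labeled by X, with every edge
carrying a finite, non-empty set of strictly positive lengths. Lengths
measure expected divergence (e.g. substitutions per site), **not time**:
no clock is assumed, and most of the theory below is specifically about
the clock-free regime. Three modelling choices deserve comment.

* **Length sets.** After reticulate events, a single edge of the drawn
  network can summarise several distinct paths of the true history with
  different accumulated divergence. A k-valued length set is exactly
  equivalent to a k-fold multiedge; the set form is the normal form here,
  and `parse_network()` folds multiedge input into it on sight.
* **Roots of outdegree 1.** Networks are rooted by an (omitted) outgroup,
  and trimming the outgroup lineage can leave a stem edge above the first
  split; both networks and displayed trees may therefore have an
  outdegree-1 root, written in Newick as a trailing `:length`.
* **Mixed-degree nodes.** Nodes with indegree > 1 *and* outdegree > 1 are
  allowed. They arise naturally in canonical forms, where a cascade of
  unresolvable reticulations collapses onto the following split.

A *switching* keeps one in-edge per reticulation and one length per edge;
pruning unlabeled dead ends gives a *contained tree*, and suppressing
indegree-1/outdegree-1 nodes (adding lengths, so root–leaf distances are
invariant) gives a *displayed tree*. `displayed_trees()` enumerates
switchings directly and deduplicates up to isomorphism; the number of
switchings is the product of reticulation indegrees and length-set sizes,
which is exponential in the worst case, so enumeration refuses beyond a
cap (default 1e6, overridable) rather than truncating silently.

## Why exact rationals

Funnel suppression replaces lengths by Minkowski set-sums, and the NELP
property (below) asks whether two path sums are *exactly* equal; both are
equality-sensitive, and binary floating point cannot represent inputs as
simple as 0.1 exactly. All lengths are therefore parsed from text into
exact rationals (numerator/denominator pairs reduced by gcd, stored in
doubles, with a hard error rather than silent wraparound past 2^53), and
all comparisons, sums and unions are exact. Terminating decimals print
back exactly as decimals, other rationals as `p/q`, so text round-trips
are bit-stable. A tolerance-based comparison is deliberately *not* the
default anywhere; floating-point input is accepted only through its
printed decimal form.

## The reduction and its guarantees

`canonicalize()` applies two rules until neither fires: **R1** removes a
funnel (indegree ≥ 1, outdegree 1), joining each parent to the child with
set-sum lengths; **R2** merges parallel edges by union. Each step removes
one edge, so at most |E| steps run. The package treats the following as
*tested invariants* rather than assumptions (see `test-canonical.R` and
`test-acceptance.R`):

* the output is funnel-free and simple, and displays exactly the same
  weighted trees as the input — checked on every catalogued example and
  on 300 random networks per run;
* the end result is independent of rule order — the deterministic
  scheduler (R2 eagerly, else the lexicographically first funnel) is
  compared against a seeded random scheduler;
* inserting funnels at random (`zip_insert_funnel()`, the constructive
  inverse of R1, and its driver `random_funnelize()`) never changes the
  canonical form — 500 draws per run;
* NELP survives reduction.

Intermediate states may carry genuine multiedges; they are flagged
(`multiedge_mode`) and confined to the inside of the reduction. Public
outputs are always simple networks.

## NELP, wishbones and cracks

A network satisfies **NELP** (*no equally long paths*) if no two distinct
weighted paths with the same endpoints have equal total length — where
paths differing only in the length chosen on a multi-valued edge count as
distinct. Under NELP the canonical form is unique up to isomorphism, so
`indistinguishable(..., mode = "canonical")` may simply compare canonical
forms; without NELP that equivalence genuinely fails (the catalogued
clock-like family `fig10_a/b/c` is pairwise indistinguishable, pairwise
non-isomorphic, and funnel-free), so canonical mode refuses NELP
violators and points to direct enumeration instead. `check_nelp()`
returns a concrete witness pair on violation, found by exhaustive
per-source path enumeration with exact totals — quadratic blowup is
capped explicitly (default 1e5 weighted paths per source).

For lengths drawn from a continuous distribution NELP holds with
probability one; it fails systematically when lengths are clock-like
(all root-to-node paths equally long). The uniqueness theory rests on two
enumerable families of sub-networks: *wishbones* (unions of two root-leaf
weighted paths sharing only a prefix) and *cracks* (sharing only a prefix
and a suffix; a path with two lengths attributed to one edge is the
degenerate bubble). For NELP networks, equality of the wishbone and crack
sets up to isomorphism characterises isomorphism — a property the test
suite verifies bidirectionally on a small corpus against an independent
shape-based subgraph scan. These enumerations are exponential by nature
and exist for verification at desk scale, not as practical isomorphism
tests; `are_isomorphic()` itself uses canonical codes plus backtracking.

## Canonical codes and isomorphism

Networks are compared up to isomorphism fixing leaf labels only; internal
identifiers never carry meaning. `network_canonical_code()` expands each
node bottom-up into a sorted bracket string over (length-set, child-code)
pairs, memoized per node, prefixed with node/edge counts and degree and
reticulation summaries. For trees this code is a complete invariant; for
DAGs bottom-up codes alone are not (distinct nodes can share identical
descendant structure), so `are_isomorphic()` treats code equality as a
filter and always confirms with a signature-guided backtracking bijection
search. An exhaustive permutation oracle (`brute_force_isomorphic()`,
guarded at 12 nodes) provides the independent ground truth in tests; the
three routes are required to agree on hundreds of random pairs per run.

## Scoring demonstrations

`network_parsimony()` and `network_likelihood()` implement the two
displayed-tree scores. They exist to make the identifiability statement
executable — indistinguishable networks receive identical scores for
*every* input, which the tests check over 50 random alignments per run —
not to be competitive inference tools. Tree-level small parsimony uses
Hartigan's bottom-up algorithm (exact for multifurcating rooted trees,
which displayed trees often are); tree likelihood uses Felsenstein
pruning under the simplest equal-rates substitution model with uniform
root frequencies, since score *equality*, not model realism, is the
point. Both are cross-checked in the test suite against exhaustive
ancestral-state enumeration and against `phangorn` on binary trees.
Likelihood requires single-valued length sets: a multi-valued edge
summarises several histories and has no single per-tree probability; such
input is refused with that explanation. Inheritance probabilities are
given per reticulation in-edge and must sum to one at each reticulation;
the induced distribution over displayed trees (`tree_distribution()`)
sums switching probabilities by resulting tree.

## The generator and what it does (not) emulate

`random_network()` grows a random binary tree by uniform joins and adds
each reticulation by subdividing two random edges and linking the new
nodes, rejecting placements that would close a cycle. This mirrors how
reticulate histories are usually drawn (each event splices a donor
lineage into a recipient edge) and produces the typical case where every
reticulation is born a funnel. Branch lengths come from a uniform grid of
rationals with denominator 1e6 on (0, 1]: dense enough that equal path
sums essentially never happen by chance (the NELP-genericity rate is
measured each run), while keeping all downstream arithmetic — set sums in
R1, shifts in zip/unzip, path totals — exactly representable far from the
overflow guard. Deltas for `random_funnelize()` are drawn on the same
grid for the same reason.

What the generator does *not* emulate: non-uniform tree shapes (birth–
death or coalescent), rate heterogeneity, clock-like lengths, or
reticulations constrained to contemporaneous lineages. Consequently,
passing property suites says the algorithms are correct on generic
divergence-scaled networks; it says nothing about, e.g., the uniqueness
of canonical forms for time-calibrated networks — which is false, as the
catalogued clock-like family shows.

## The catalogued examples

`paper_fixture()` serves a catalogue of small networks covering each
corner of the theory; all are also shipped as extended-Newick files under
`inst/extdata/fixtures/`. The fig3 family deserves detail because it
doubles as a transcription self-check: `fig3_N1` (symbolic lengths
λ1..λ12, instantiated as λi = i by default — distinct integers chosen so
the family satisfies NELP, which the tests confirm) has exactly two
funnels in series above leaf b, and its weighted-path structure
reproduces the catalogued sums λ1+λ6, λ2+λ3+λ5+λ8, λ2+λ10+λ9+λ8 between
the root and b's direct ancestor, and λ3+λ5, λ10+λ9 between the inner
pair. `fig3_N2` swaps the order of the two reticulate events; its edge
lengths are *derived*, not free: writing the shared canonical form's
three parent-to-b sums and re-splitting them in the opposite order forces
edges λ6−x, λ5+λ8−x, x+y, λ8+λ9+y, λ7−y, whose positivity conditions are
exactly the admissibility bounds −y < x < min(λ6, λ5+λ8) and 0 < y < λ7
exposed by `paper_fixture("fig3_N2", x =, y =)`. Every admissible (x, y)
yields a network indistinguishable from `fig3_N1` — the order of
consecutive reticulations and the funnel out-edge lengths are precisely
what displayed trees cannot see.

`fig5_N` shows the phenomenon beyond the classical restricted classes: it
is not tree-child (two of its nodes have only reticulation children), not
tree-sibling (one reticulation has only reticulation siblings), and has a
reticulation avoidable from every leaf, yet it displays seven distinct
weighted trees and is determined by them up to the lengths x, y, z of its
three funnel out-edges (defaults 0.05, anywhere in (0, 0.1)); its
canonical form collapses exactly those three edges and contains a node
with indegree 2 and outdegree 2. Where a figure's published drawing
carries numeric lengths that are not restated in any text the package can
cite, the fixture's remaining lengths are documented synthetic defaults,
and no test depends on them — tests assert only catalogued counts and
properties (seven trees, three suppressions, class memberships), which
hold for any generic choice.

## Numerical and design choices

* Deterministic everything: children are written in canonical-code order,
  switchings and funnels are processed in sorted order, and every
  stochastic routine takes a local seed that does not disturb the global
  RNG state.
* Degenerate inputs are first-class: a single labeled leaf is a valid
  network (`"a;"`), roots of outdegree 1 round-trip, and suppression
  never removes the root.
* Enumeration guards fail loudly (`"cap exceeded"`) and are plain
  arguments, not options; nothing is ever silently truncated.
* Ties in sorting rationals are broken by exact cross-multiplication;
  the double-precision ratio is only a sort key accelerator.
* `zip_insert_funnel()` requires its delta strictly below every affected
  length value, so zero-length edges can never arise; `unzip()` allows
  delta equal to the out-edge length, in which case the reticulation
  merges with its child (the boundary case of the operation).

## Known limitations

* All displayed-tree and path enumerations are exponential in the number
  of reticulations and length-set sizes; the package is a desk-scale
  research tool, correct-by-construction, not a big-data engine.
* The conjecture that a funnel-free NELP network can never be
  indistinguishable from a funnel-free NELP-violating one is left open in
  the underlying theory; the package exposes the pieces to search for
  counterexamples (`indistinguishable()` + `check_nelp()`) and assumes
  nothing about it.
* Likelihood is a demonstration under one fixed substitution model;
  there is no model choice, no rate variation, and no optimisation of
  lengths or inheritance probabilities — network inference is explicitly
  out of scope.
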