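# phylocanon

Canonical forms, displayed trees and identifiability for weighted rooted
phylogenetic networks.

## The problem

Explicit phylogenetic networks describe evolution with reticulate events —
hybrid speciation, horizontal gene transfer, recombination — as rooted DAGs
whose leaves are the sampled taxa. Each non-recombining character still
evolves down a *tree*, so inference methods score a candidate network
`N` through the set `T(N)` of weighted trees it *displays*: keep one
in-edge per reticulation, pick one length per edge, prune dead ends, and
suppress degree-two nodes (summing lengths). Standard network parsimony
and likelihood are

```
Ps(N | A1..Am) = Σ_i min_{T ∈ T(N)} Ps(T | A_i)
Pr(A1..Am | N) = Π_i Σ_{T ∈ T(N)} Pr(A_i | T) Pr(T | N)
```

which depend on `N` only through `T(N)`. Networks displaying the same
trees are therefore **indistinguishable**: no amount of data can separate
them. The culprit is the *funnel* — a node with indegree ≥ 1 and
outdegree 1. Length can be shifted freely between a funnel's out-edge and
its in-edges ("unzipping") without changing a single displayed tree, so
funnel positions and out-edge lengths are unidentifiable in principle.

This package implements the resolution of that problem: every network
reduces, by two local rewrite rules, to a **canonical form** — funnel-free,
displaying exactly the same weighted trees — and under a mild genericity
condition (*NELP*: no two distinct weighted paths with the same endpoints
have equal total length) that canonical form is *unique up to isomorphism*.
Canonical networks are exactly what displayed-tree-based inference can
hope to reconstruct. The two rules are

* **R1 (funnel suppression)** — remove funnel `v`; join each parent `u_i`
  directly to the child `w` with the Minkowski set-sum of lengths,
  `Λ(u_i,w) = Λ(u_i,v) + Λ(v,w)`;
* **R2 (multiedge merging)** — replace parallel edges by one edge carrying
  the union of their length sets.

Edges carry finite *sets* of positive lengths (a k-length edge is the
compact form of a k-fold multiedge); all lengths are exact rationals, so
set sums and path-length comparisons are never at the mercy of floating
point.

Who this is for: developers of network inference methods who need to
restrict their search space to identifiable networks, and anyone studying
what is — and provably is not — recoverable about reticulate evolution
from displayed-tree criteria.

## A worked example

A network on taxa a–d in the package's extended-Newick dialect (`#H` tags
mark reticulations; `:{x,y}` writes a length set):

```r
library(phylocanon)
net <- parse_network(
  "((a:4,(b:7)#H1:6):1,((d:12,(#H1:8)#H2:9):10,(c:11,#H2:5):3):2);")
funnel_nodes(net)
#> [1] ".H1" ".H2"
```

Both reticulations are funnels, so `net` is not canonical. It displays
three weighted trees — the three possible histories of the hybrid leaf b:

```r
cat(vapply(displayed_trees(net), write_tree, character(1)), sep = "\n")
#> ((b:13,a:4):1,(c:14,d:22):2);
#> (((d:12,b:24):10,c:14):2,a:5);
#> ((d:22,(c:11,b:20):3):2,a:5);
```

Reduction to canonical form takes two funnel suppressions and leaves the
displayed trees untouched; afterwards b is a reticulation leaf with three
parents, which is precisely the identifiable content of the network:

```r
res <- canonicalize(net)
res$trace
#>   rule target       before     after
#> 1   R1    .H1  {6} {8} {7} {13} {15}
#> 2   R1    .H2 {9} {5} {15} {24} {20}
write_network(res$network)
#> [1] "((b#H1:13,a:4):1,((d:12,b#H1:24):10,(c:11,b#H1:20):3):2);"
check_nelp(net)$nelp   # generic lengths: the canonical form is unique
#> [1] TRUE
```

`indistinguishable(n1, n2, mode = "canonical")` decides indistinguishability
by comparing canonical forms (valid under NELP);
`mode = "direct"` compares the enumerated tree sets and works for any
networks, including clock-like (NELP-violating) ones, for which canonical
forms need not be unique — see `paper_fixture("fig10_b")` and friends.

A command-line interface wraps the same functions:

```sh
inst/scripts/phylocanon compare --a n1.enwk --b n2.enwk --mode canonical
inst/scripts/phylocanon nelp --in net.enwk --report json
inst/scripts/phylocanon canonicalize --in net.enwk --out canon.enwk --trace trace.json
```

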