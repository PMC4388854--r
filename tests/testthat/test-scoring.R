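test_that("tree parsimony handles trivial and degenerate cases", {
  tr <- parse_tree("((a:1,b:2):1,c:3);")
  same <- alignment(c(a = "AAAA", b = "AAAA", c = "AAAA"))
  expect_equal(tree_parsimony(tr, same), 0)

  two <- parse_tree("(a:1,b:1);")
  expect_equal(tree_parsimony(two, alignment(c(a = "AA", b = "AC"))), 1)

  expect_error(tree_parsimony(tr, alignment(c(a = "A", b = "A", x = "A"))),
               "taxa")
  # additivity over columns
  a1 <- alignment(c(a = "AC", b = "AG", c = "AT"))
  a2 <- alignment(c(a = "C", b = "G", c = "T"))
  a3 <- alignment(c(a = "A", b = "A", c = "A"))
  expect_equal(tree_parsimony(tr, a1),
               tree_parsimony(tr, a2) + tree_parsimony(tr, a3))
})

test_that("Hartigan parsimony equals exhaustive minimisation", {
  set.seed(17)
  for (i in 1:10) {
    net <- random_network(sample(3:5, 1), sample(0:1, 1), seed = 910 + i)
    trees <- displayed_trees(net)
    tr <- trees[[sample(length(trees), 1)]]
    aln <- random_alignment(net_taxa(tr), n_sites = 4)
    expect_equal(tree_parsimony(tr, aln), brute_parsimony(tr, aln))
  }
})

test_that("tree parsimony agrees with phangorn on binary trees", {
  skip_if_not_installed("phangorn")
  set.seed(18)
  for (i in 1:5) {
    tr <- as_weighted_tree(random_network(5, 0, seed = 950 + i))
    aln <- random_alignment(net_taxa(tr), n_sites = 8)
    ph <- ape::read.tree(text = write_tree(tr))
    pd <- phangorn::phyDat(do.call(rbind, lapply(unclass(aln), function(s)
      strsplit(s, "")[[1]])), type = "DNA")
    expect_equal(tree_parsimony(tr, aln),
                 as.integer(phangorn::parsimony(ph, pd)))
  }
})

test_that("network parsimony is the per-alignment min over displayed trees", {
  tr <- parse_tree("((a:1,b:2):1,c:3);")
  alns <- lapply(1:3, function(i) random_alignment(c("a", "b", "c"), 6,
                                                   seed = 40 + i))
  expect_equal(network_parsimony(tr, alns),
               sum(vapply(alns, function(a) tree_parsimony(tr, a), 0L)))

  net <- paper_fixture("fig3_N1")
  alns4 <- lapply(1:4, function(i) random_alignment(net_taxa(net), 6,
                                                    seed = 50 + i))
  # exchanging min and sum can only lower the score
  trees <- displayed_trees(net)
  per_tree <- vapply(trees, function(tr)
    sum(vapply(alns4, function(a) tree_parsimony(tr, a), 0L)), 0L)
  expect_lte(network_parsimony(net, alns4), min(per_tree))
})

test_that("indistinguishable networks score identically, always", {
  n1 <- paper_fixture("fig3_N1"); n2 <- paper_fixture("fig3_N2")
  f10 <- lapply(c("fig10_a", "fig10_b", "fig10_c"), paper_fixture)
  for (i in 1:50) {
    a4 <- random_alignment(c("a", "b", "c", "d"), 8, seed = 1100 + i)
    expect_identical(network_parsimony(n1, a4), network_parsimony(n2, a4))
    a2 <- random_alignment(c("a", "b"), 8, seed = 1200 + i)
    s <- vapply(f10, network_parsimony, 0L, alignments = a2)
    expect_true(all(s == s[1]))
  }
})

test_that("JC pruning equals brute-force summation over ancestral states", {
  set.seed(19)
  for (i in 1:6) {
    tr <- as_weighted_tree(random_network(sample(3:4, 1), 0, seed = 970 + i))
    aln <- random_alignment(net_taxa(tr), n_sites = 3)
    expect_equal(tree_likelihood(tr, aln), brute_likelihood(tr, aln),
                 tolerance = 1e-12)
  }
})

test_that("tree likelihood agrees with phangorn's JC pruning", {
  skip_if_not_installed("phangorn")
  set.seed(23)
  tr <- as_weighted_tree(random_network(5, 0, seed = 981))
  aln <- random_alignment(net_taxa(tr), n_sites = 10)
  ph <- ape::read.tree(text = write_tree(tr))
  pd <- phangorn::phyDat(do.call(rbind, lapply(unclass(aln), function(s)
    strsplit(s, "")[[1]])), type = "DNA")
  fit <- phangorn::pml(ph, pd)
  expect_equal(log(tree_likelihood(tr, aln)), as.numeric(fit$logLik),
               tolerance = 1e-6)
})

test_that("tree distributions and network likelihood behave as probabilities", {
  net <- paper_fixture("fig3_N1")
  probs <- c("n->vb" = 0.3, "m->vb" = 0.7, "s->m" = 0.4, "t->m" = 0.6)
  td <- tree_distribution(net, probs)
  expect_equal(sum(td$prob), 1)
  expect_true(all(td$prob >= 0))
  # the switching that picks the n-side prunes the lower reticulation, so
  # its whole probability mass lands on one tree
  expect_true(any(abs(td$prob - 0.3) < 1e-12))

  aln <- random_alignment(net_taxa(net), 5, seed = 3)
  ll <- network_likelihood(net, probs, aln)
  expect_gt(ll, 0); expect_lte(ll, 1)

  # a tree's network likelihood is the product of its tree likelihoods
  tr <- parse_tree("((a:1,b:2):1,c:3);")
  alns <- lapply(1:2, function(i) random_alignment(c("a", "b", "c"), 4,
                                                   seed = 70 + i))
  expect_equal(network_likelihood(tr, stats::setNames(numeric(0), character(0)),
                                  alns),
               prod(vapply(alns, function(a) tree_likelihood(tr, a), 0)),
               tolerance = 1e-12)

  # invariant under internal relabeling (same displayed trees and probs)
  relab <- parse_network(write_network(net))
  ekey <- function(n) paste0(n$from, "->", n$to)
  # rebuild the probability map for the relabeled reticulation in-edges
  rets <- reticulation_nodes(relab)
  probs2 <- stats::setNames(numeric(0), character(0))
  for (v in rets) {
    ids <- edge_ids_in(relab, v)
    # match by (length set, child) signature, unique here
    for (i in ids) {
      orig <- which(vapply(net$lengths, ls_key, "") ==
                      ls_key(relab$lengths[[i]]))
      probs2[ekey(relab)[i]] <- probs[ekey(net)[orig]]
    }
  }
  expect_equal(network_likelihood(relab, probs2, aln),
               network_likelihood(net, probs, aln), tolerance = 1e-12)

  # multi-valued lengths are refused with guidance
  expect_error(tree_distribution(paper_fixture("fig13_end"),
                                 c("u2->w" = 0.5, "r->w" = 0.5)),
               "single-valued")
  # probabilities must normalise per reticulation
  expect_error(tree_distribution(net, c("n->vb" = 0.5, "m->vb" = 0.7,
                                        "s->m" = 0.4, "t->m" = 0.6)),
               "sum to 1")
})
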