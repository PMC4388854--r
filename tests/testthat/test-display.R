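test_that("contained trees keep the root, taxa and chosen lengths", {
  n1 <- paper_fixture("fig3_N1")
  # both reticulations toward their left-listed parents
  rets <- reticulation_nodes(n1)
  s <- switching(stats::setNames(
    vapply(rets, function(v) edge_ids_in(n1, v)[1], 1L), rets))
  tr <- contained_tree(n1, s)
  expect_s3_class(tr, "phylo_tree")
  expect_setequal(net_taxa(tr), net_taxa(n1))
  expect_equal(net_root(tr), net_root(n1))
  # suppressible nodes remain until suppress_all
  expect_true(any(net_indegree(tr) == 1 & net_outdegree(tr) == 1))

  # a tree is its own (only) contained tree
  t0 <- parse_tree("((a:1,b:2):1,c:3);")
  s0 <- switching(stats::setNames(integer(0), character(0)))
  expect_true(are_isomorphic(contained_tree(t0, s0), t0))
})

test_that("dead-end branches are pruned from contained trees", {
  # if the funnel above b takes its left parent, the whole m-side chain
  # dangles and must be deleted
  n1 <- paper_fixture("fig3_N1")
  s <- switching(c(m = edge_ids_in(n1, "m")[1],
                   vb = which(n1$from == "n" & n1$to == "vb")))
  tr <- contained_tree(n1, s)
  expect_false("m" %in% tr$nodes)
})

test_that("suppression sums lengths, keeps the root, and is order-free", {
  chain <- as_weighted_tree(phylo_network(
    rbind(c("r", "v"), c("v", "leaf")), list(1, 2)))
  out <- suppress_all(chain)
  expect_equal(n_edges(out), 1)
  expect_equal(ls_key(out$lengths[[1]]), "{3}")

  t0 <- parse_tree("((a:1,b:2):1,c:3);")
  expect_true(are_isomorphic(suppress_all(t0), t0))

  # order independence: many random suppression orders reach the same tree
  n1 <- paper_fixture("fig3_N1")
  rets <- reticulation_nodes(n1)
  s <- switching(stats::setNames(
    vapply(rets, function(v) edge_ids_in(n1, v)[2], 1L), rets))
  base <- contained_tree(n1, s)
  ref <- suppress_all(base)
  set.seed(4)
  for (i in 1:10) {
    tr <- base
    repeat {
      ind <- net_indegree(tr); outd <- net_outdegree(tr)
      vs <- tr$nodes[ind == 1 & outd == 1]
      if (!length(vs)) break
      v <- sample(vs, 1)
      ei <- edge_ids_in(tr, v); eo <- edge_ids_out(tr, v)
      u <- tr$from[ei]; w <- tr$to[eo]
      l <- ls_sum(tr$lengths[[ei]], tr$lengths[[eo]])
      tr <- drop_edges(tr, c(ei, eo))
      tr$nodes <- setdiff(tr$nodes, v)
      tr <- add_edge(tr, u, w, l)
    }
    expect_true(are_isomorphic(as_weighted_tree(tr), ref))
  }
})

test_that("displayed-tree sets have the right size and members", {
  expect_equal(length(displayed_trees(paper_fixture("fig3_N1"))), 3)
  expect_equal(length(displayed_trees(paper_fixture("fig5_N"))), 7)
  # a weighted tree displays exactly itself
  t0 <- parse_tree("((a:1,b:2):1,c:3);")
  dt <- displayed_trees(t0)
  expect_length(dt, 1)
  expect_true(are_isomorphic(dt[[1]], t0))
  # every displayed tree is displayed
  n <- paper_fixture("fig5_N")
  for (tr in displayed_trees(n)) expect_true(displays(n, tr))
  # switching-count upper bound
  expect_lte(length(displayed_trees(n)), switching_space_size(n))
  # enumeration cap refuses explicitly
  expect_error(displayed_trees(n, cap = 2), "cap")
})

test_that("root-leaf distances of displayed trees exist in the network", {
  net <- random_network(4, 2, seed = 77)
  r <- net_root(net)
  for (tr in displayed_trees(net)) {
    for (lf in net_taxa(tr)) {
      d <- weighted_paths_between(tr, net_root(tr), lf)[[1]]$total
      cand <- weighted_paths_between(net, r, lf)
      expect_true(any(vapply(cand, function(p)
        isTRUE(rat_eq(p$total, d)), TRUE)))
    }
  }
})

test_that("fig7: the trimmed network displays exactly its two trees", {
  n <- paper_fixture("fig7_N2prime")
  expect_true(displays(n, paper_fixture("fig7_T1prime")))
  expect_true(displays(n, paper_fixture("fig7_T2prime")))
  expect_length(displayed_trees(n), 2)
})

test_that("fig2: only the matching cycle can display both weighted trees", {
  T1 <- paper_fixture("fig2_T1"); T2 <- paper_fixture("fig2_T2")
  n2 <- paper_fixture("fig2_N2")
  expect_true(displays(n2, T1) && displays(n2, T2))
  set.seed(12)
  for (i in 1:100) {
    lens <- sample(1e6, 9, replace = TRUE) / 1e6
    m <- paper_fixture("fig2_N1", lens = lens)
    expect_false(displays(m, T1) && displays(m, T2))
  }
})

test_that("displays warns and refuses on taxon mismatch", {
  n <- paper_fixture("fig3_N1")
  expect_warning(res <- displays(n, parse_tree("(a:1,b:1);")), "taxon")
  expect_false(res)
})

test_that("direct and canonical indistinguishability agree under NELP", {
  n1 <- paper_fixture("fig3_N1")
  # caption-compliant (x, y) draws: -y < x < min(l6, l5+l8), 0 < y < l7
  set.seed(3)
  for (i in 1:5) {
    y <- rational(sample(6999L, 1), 1000)          # (0, 7)
    xlo <- -y$num / y$den
    x <- rational(sample(seq(floor(xlo * 1000) + 1L, 5999L), 1), 1000)
    n2 <- paper_fixture("fig3_N2", x = x, y = y)
    expect_true(indistinguishable(n1, n2, mode = "direct"))
    expect_true(indistinguishable(n1, n2, mode = "canonical"))
  }
  # any network vs its canonical form
  for (nm in c("fig3_N1", "fig5_N", "fig13_start")) {
    net <- paper_fixture(nm)
    expect_true(indistinguishable(net, canonicalize(net)$network))
  }
  # the clock-like family: indistinguishable, not isomorphic; canonical
  # mode refuses because NELP fails
  a <- paper_fixture("fig10_a"); b <- paper_fixture("fig10_b")
  expect_true(indistinguishable(a, b))
  expect_false(are_isomorphic(a, b))
  expect_error(indistinguishable(a, b, mode = "canonical"), "NELP")
})
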