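test_that("R1 forms Minkowski set-sums and removes exactly one edge", {
  net <- phylo_network(rbind(c("r", "u1"), c("r", "u2"), c("u1", "v"),
                             c("u2", "v"), c("v", "w"), c("w", "a"),
                             c("w", "b")),
                       list(1, 1, 2, 3, 1, 1, 1))
  out <- apply_r1(net, "v")
  expect_false("v" %in% out$nodes)
  expect_equal(n_edges(out), n_edges(net) - 1)
  k <- vapply(out$lengths, ls_key, character(1))
  expect_true(all(c("{3}", "{4}") %in% k))
  expect_length(funnel_nodes(out), length(funnel_nodes(net)) - 1)

  # multi-valued in/out: {1,2} + {1,2} = {2,3,4}
  net2 <- phylo_network(rbind(c("r", "v"), c("v", "w"), c("w", "a"),
                              c("w", "b"), c("r", "c")),
                        list(c(1, 2), c(1, 2), 1, 1, 1))
  out2 <- apply_r1(net2, "v")
  expect_true("{2,3,4}" %in% vapply(out2$lengths, ls_key, character(1)))

  expect_error(apply_r1(net, "w"), "not a funnel")
})

test_that("R1 can create a multiedge which R2 then merges", {
  net <- paper_fixture("fig13_start")
  step1 <- apply_r1(net, "v")
  expect_true(step1$multiedge_mode)
  ids <- which(step1$from == "u1" & step1$to == "w")
  expect_length(ids, 2)
  step2 <- apply_r2(step1, "u1", "w")
  expect_false(step2$multiedge_mode)
  expect_equal(ls_key(step2$lengths[[which(step2$from == "u1" &
                                             step2$to == "w")]]), "{1,2}")
  expect_error(apply_r2(step2, "u1", "w"), "no multiedge")
})

test_that("R2 merges unions, including triple multiedges, in one step", {
  net <- phylo_network(rbind(c("r", "w"), c("r", "w"), c("r", "w"),
                             c("w", "a"), c("w", "b")),
                       list(c(1, 2), c(2, 3), 5, 1, 1),
                       multiedge_mode = TRUE)
  out <- apply_r2(net, "r", "w")
  expect_equal(sum(out$from == "r" & out$to == "w"), 1)
  expect_equal(ls_key(out$lengths[[which(out$from == "r" & out$to == "w")]]),
               "{1,2,3,5}")
})

test_that("canonicalize reaches the documented canonical forms", {
  np <- paper_fixture("fig4_Nprime")
  expect_true(are_isomorphic(canonicalize(paper_fixture("fig3_N1"))$network, np))
  expect_true(are_isomorphic(canonicalize(paper_fixture("fig3_N2"))$network, np))

  res <- canonicalize(paper_fixture("fig13_start"))
  expect_true(are_isomorphic(res$network, paper_fixture("fig13_end")))
  expect_equal(res$trace$rule, c("R1", "R2", "R1"))

  # funnel-free input is a fixed point with an empty trace
  res2 <- canonicalize(np)
  expect_true(are_isomorphic(res2$network, np))
  expect_equal(nrow(res2$trace), 0)

  # idempotence
  c1 <- canonicalize(paper_fixture("fig5_N"))$network
  expect_true(are_isomorphic(canonicalize(c1)$network, c1))
})

test_that("canonicalize output is funnel-free, simple, and step-bounded", {
  set.seed(21)
  for (i in 1:20) {
    net <- random_funnelize(random_network(4, sample(0:2, 1), seed = 400 + i),
                            k = sample(1:2, 1))
    res <- canonicalize(net)
    expect_true(is_funnel_free(res$network))
    expect_false(res$network$multiedge_mode)
    expect_length(validate_network(res$network), 0)
    expect_lte(nrow(res$trace), n_edges(net))
    expect_true(setequal(names(displayed_trees(net)),
                         names(displayed_trees(res$network))))
  }
})

test_that("rule order does not change the end result (confluence)", {
  for (nm in c("fig3_N1", "fig5_N", "fig13_start")) {
    net <- paper_fixture(nm)
    ref <- canonicalize(net)$network
    for (s in 1:3)
      expect_true(are_isomorphic(
        canonicalize(net, order = "random", seed = s)$network, ref))
  }
})

test_that("unzip shifts length without changing the displayed trees", {
  n1 <- paper_fixture("fig3_N1")
  expect_error(unzip(n1, "vb", 0), "delta")
  expect_error(unzip(n1, "vb", 8), "delta")   # out-edge has length 7
  expect_error(unzip(n1, "n", 1), "reticulation")

  half <- unzip(n1, "vb", "3.5")
  expect_true("vb" %in% half$nodes)
  expect_true(setequal(names(displayed_trees(half)),
                       names(displayed_trees(n1))))

  # full unzip merges the reticulation with its child; doing both
  # reticulations reaches the canonical form
  full <- unzip(unzip(n1, "vb", 7), "m", 15)
  expect_false(any(c("vb", "m") %in% full$nodes))
  expect_true(are_isomorphic(full, paper_fixture("fig4_Nprime")))

  # multi-valued lengths on touched edges are refused
  n13 <- paper_fixture("fig13_end")
  skip_if(length(reticulation_nodes(n13)) == 0)

  # property: displayed trees invariant over random (network, delta) draws
  set.seed(9)
  for (i in 1:25) {
    net <- random_funnelize(rand_canonical_base(600 + i), 1)
    rets <- reticulation_nodes(net)
    outd <- net_outdegree(net)
    cand <- rets[outd[rets] == 1]
    cand <- cand[vapply(cand, function(v)
      all(vapply(net$lengths[c(edge_ids_in(net, v), edge_ids_out(net, v))],
                 length, 1L) == 1L), TRUE)]
    if (!length(cand)) next
    v <- cand[1]
    out_len <- net$lengths[[edge_ids_out(net, v)]]
    hi <- floor(out_len$num / out_len$den * 1e6)
    delta <- rational(sample(hi, 1), 1e6)
    expect_true(setequal(names(displayed_trees(unzip(net, v, delta))),
                         names(displayed_trees(net))))
  }
})

test_that("zip_insert_funnel is the constructive inverse of R1", {
  np <- paper_fixture("fig4_Nprime")
  ids <- edge_ids_in(np, "b")
  z <- zip_insert_funnel(np, "b", ids[1:2], 3)
  expect_length(funnel_nodes(z), 1)
  expect_true(are_isomorphic(canonicalize(z)$network, np))
  expect_error(zip_insert_funnel(np, "b", ids, 100), "strictly below")

  # zipping a single in-edge creates a suppressible funnel
  z1 <- zip_insert_funnel(np, "a", edge_ids_in(np, "a"), 1)
  fn <- funnel_nodes(z1)
  expect_length(fn, 1)
  expect_equal(unname(net_indegree(z1)[fn]), 1L)

  # repeated zipping rebuilds a two-funnel sibling of the fig3 family
  z2 <- zip_insert_funnel(np, "b", ids[2:3], 2)
  v <- setdiff(z2$nodes, np$nodes)
  z2 <- zip_insert_funnel(z2, "b", edge_ids_in(z2, "b"), 1)
  expect_length(funnel_nodes(z2), 2)
  expect_true(indistinguishable(z2, paper_fixture("fig3_N1")))

  # property: zip then canonicalize returns the original canonical form
  set.seed(10)
  for (i in 1:25) {
    base <- rand_canonical_base(800 + i)
    fz <- random_funnelize(base, sample(1:3, 1))
    expect_gte(length(funnel_nodes(fz)), 1)
    expect_true(are_isomorphic(canonicalize(fz)$network, base))
  }
})
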