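# Independent oracles used to cross-check the package implementations on
# small instances. These deliberately use the most naive formulation of
# each quantity (exhaustive enumeration) and share no code with the
# functions they check.

expect_iso <- function(a, b) expect_true(are_isomorphic(a, b))

# exhaustive small-parsimony: minimise changes over all ancestral state
# assignments drawn from the full DNA alphabet
brute_parsimony <- function(tree, aln) {
  m <- do.call(rbind, lapply(unclass(aln), function(s) strsplit(s, "")[[1]]))
  internal <- setdiff(tree$nodes, net_leaves(tree))
  bases <- c("A", "C", "G", "T")
  total <- 0L
  for (col in seq_len(ncol(m))) {
    grid <- do.call(expand.grid,
                    c(rep(list(bases), length(internal)),
                      list(stringsAsFactors = FALSE)))
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      st <- c(stats::setNames(as.character(grid[g, ]), internal),
              stats::setNames(m[, col], rownames(m)))
      ch <- sum(st[tree$from] != st[tree$to])
      best <- min(best, ch)
    }
    total <- total + best
  }
  total
}

# exhaustive JC likelihood: sum over all internal-node states
brute_likelihood <- function(tree, aln) {
  m <- do.call(rbind, lapply(unclass(aln), function(s) strsplit(s, "")[[1]]))
  internal <- setdiff(tree$nodes, net_leaves(tree))
  bases <- c("A", "C", "G", "T")
  pm <- lapply(seq_len(length(tree$from)), function(i) {
    l <- tree$lengths[[i]]
    t <- l$num / l$den
    e <- exp(-4 * t / 3)
    mm <- matrix(0.25 - 0.25 * e, 4, 4, dimnames = list(bases, bases))
    diag(mm) <- 0.25 + 0.75 * e
    mm
  })
  lik <- 1
  root <- net_root(tree)
  for (col in seq_len(ncol(m))) {
    grid <- do.call(expand.grid,
                    c(rep(list(bases), length(internal)),
                      list(stringsAsFactors = FALSE)))
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      st <- c(stats::setNames(as.character(grid[g, ]), internal),
              stats::setNames(m[, col], rownames(m)))
      p <- 0.25
      for (i in seq_along(tree$from))
        p <- p * pm[[i]][st[tree$from[i]], st[tree$to[i]]]
      tot <- tot + p
    }
    lik <- lik * tot
  }
  lik
}

# brute-force wishbone/crack recognition: scan all edge subsets of the
# network with all nonempty length sub-choices and classify the resulting
# subgraph purely by its shape
oracle_path_unions <- function(net) {
  ne <- length(net$from)
  stopifnot(ne <= 12)
  root <- net_root(net)
  leaves <- net_leaves(net)
  wish <- character(0); crack <- character(0)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), ne))
  for (r in seq_len(nrow(subsets))) {
    ids <- which(unlist(subsets[r, ]))
    if (!length(ids)) next
    # nonempty length sub-choices per chosen edge
    choice_lists <- lapply(ids, function(i) {
      l <- net$lengths[[i]]
      ks <- seq_len(length(l))
      subs <- list()
      for (sz in 1:length(ks))
        subs <- c(subs, utils::combn(ks, sz, simplify = FALSE))
      subs
    })
    combos <- do.call(expand.grid, lapply(choice_lists, seq_along))
    for (q in seq_len(nrow(combos))) {
      lens <- lapply(seq_along(ids), function(j)
        ls_restore(net$lengths[[ids[j]]][choice_lists[[j]][[combos[q, j]]]]))
      sub <- phylo_network(cbind(net$from[ids], net$to[ids]), lens,
                           validate = FALSE)
      cls <- classify_union_shape(sub, root, leaves)
      if (is.null(cls)) next
      code <- network_canonical_code(sub)
      if ("wishbone" %in% cls) wish <- union(wish, code)
      if ("crack" %in% cls) crack <- union(crack, code)
    }
  }
  list(wishbones = wish, cracks = crack)
}

classify_union_shape <- function(sub, root, leaves) {
  nodes <- sub$nodes
  if (!(root %in% nodes)) return(NULL)
  indeg <- table(factor(sub$to, levels = nodes))
  outdeg <- table(factor(sub$from, levels = nodes))
  if (any(indeg > 2) || any(outdeg > 2)) return(NULL)
  starts <- nodes[indeg == 0]
  ends <- nodes[outdeg == 0]
  if (!identical(as.character(starts), root)) return(NULL)
  if (!all(ends %in% leaves)) return(NULL)
  # connectivity from the root
  seen <- root; repeat {
    nb <- unique(sub$to[sub$from %in% seen])
    if (all(nb %in% seen)) break
    seen <- union(seen, nb)
  }
  if (!setequal(seen, nodes)) return(NULL)
  multi <- sum(vapply(sub$lengths, length, 1L) > 1L)
  if (any(vapply(sub$lengths, length, 1L) > 2L) || multi > 1) return(NULL)
  forks <- sum(outdeg == 2); joins <- sum(indeg == 2)
  if (length(ends) == 1 && forks == 0 && joins == 0 && multi == 0)
    return(c("wishbone", "crack"))          # a single root-leaf path
  if (length(ends) == 2 && forks == 1 && joins == 0 && multi == 0)
    return("wishbone")                       # two arms to distinct leaves
  if (length(ends) == 1 && forks == 1 && joins == 1 && multi == 0)
    return("crack")                          # bubble between fork and join
  if (length(ends) == 1 && forks == 0 && joins == 0 && multi == 1)
    return("crack")                          # one edge with two lengths
  NULL
}

rand_canonical_base <- function(seed, n_taxa = 4, rets = 1) {
  canonicalize(random_network(n_taxa, rets, seed = seed))$network
}
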