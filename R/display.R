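# Trees displayed by a network.
#
# A switching jointly picks one in-edge per reticulation and one length per
# edge. Keeping only the chosen in-edges, pruning unlabeled dead ends, and
# suppressing indegree-1/outdegree-1 nodes (summing lengths) turns the
# network into one of the weighted trees it displays. The set of displayed
# trees, deduplicated up to isomorphism, is the basis of every
# indistinguishability question in this package.

#' Construct a switching
#'
#' @param ret_edges named integer vector: for each reticulation node (name),
#'   the edge index (into the network's edge list) of the chosen in-edge.
#' @param len_choice integer vector with one entry per network edge choosing
#'   an element of its length set (defaults to 1, the smallest value).
#' @return an object of class `switching`.
#' @export
switching <- function(ret_edges, len_choice = NULL) {
  structure(list(ret_edges = ret_edges, len_choice = len_choice),
            class = "switching")
}

validate_switching <- function(net, s) {
  rets <- reticulation_nodes(net)
  if (!setequal(names(s$ret_edges), rets))
    stop("switching must choose one in-edge for exactly the reticulations",
         call. = FALSE)
  for (v in rets) {
    i <- s$ret_edges[[v]]
    if (!(i %in% edge_ids_in(net, v)))
      stop("chosen edge is not an in-edge of reticulation ", v, call. = FALSE)
  }
  if (!is.null(s$len_choice)) {
    sizes <- vapply(net$lengths, length, 1L)
    if (length(s$len_choice) != n_edges(net) ||
        any(s$len_choice < 1L | s$len_choice > sizes))
      stop("length choice out of range", call. = FALSE)
  }
  invisible(TRUE)
}

#' Tree contained in a network under a switching
#'
#' Drops the unchosen reticulation in-edges, iteratively deletes unlabeled
#' dead-end nodes, and assigns each retained edge its chosen length. The
#' result is a weighted tree on exactly the network's taxa, rooted at the
#' network's root, possibly with suppressible nodes.
#'
#' @param net a valid `phylo_network`.
#' @param s a [switching()].
#' @return a `phylo_tree` (suppressible nodes allowed).
#' @export
contained_tree <- function(net, s) {
  validate_switching(net, s)
  drop <- setdiff(unlist(lapply(names(s$ret_edges), function(v)
    edge_ids_in(net, v))), unname(s$ret_edges))
  len_choice <- if (is.null(s$len_choice)) rep(1L, n_edges(net)) else s$len_choice
  keep <- setdiff(seq_len(n_edges(net)), drop)
  from <- net$from[keep]; to <- net$to[keep]
  lens <- lapply(keep, function(i) net$lengths[[i]][len_choice[i]])
  nodes <- net$nodes
  taxa <- net_leaves(net)
  repeat {
    has_out <- nodes %in% from
    dead <- nodes[!has_out & !(nodes %in% taxa)]
    dead <- setdiff(dead, net_root(net))
    if (!length(dead)) break
    kill <- to %in% dead
    from <- from[!kill]; to <- to[!kill]; lens <- lens[!kill]
    nodes <- setdiff(nodes, dead)
  }
  tr <- phylo_network(cbind(from, to), lens, nodes = nodes, validate = TRUE)
  as_weighted_tree(tr)
}

#' Suppress all suppressible nodes of a tree
#'
#' A node with indegree 1 and outdegree 1 is replaced by a single edge whose
#' length is the sum of the two incident edge lengths, so root-to-leaf
#' distances are preserved. The root (indegree 0) is never suppressed, even
#' at outdegree 1. The result does not depend on the order of suppression.
#'
#' @param tree a `phylo_tree`, possibly with suppressible nodes.
#' @return a `phylo_tree` with no suppressible nodes.
#' @export
suppress_all <- function(tree) {
  repeat {
    ind <- net_indegree(tree); outd <- net_outdegree(tree)
    v <- tree$nodes[ind == 1L & outd == 1L]
    if (!length(v)) break
    v <- v[1]
    e_in <- edge_ids_in(tree, v); e_out <- edge_ids_out(tree, v)
    u <- tree$from[e_in]; w <- tree$to[e_out]
    newlen <- ls_sum(tree$lengths[[e_in]], tree$lengths[[e_out]])
    tree <- drop_edges(tree, c(e_in, e_out))
    tree$nodes <- setdiff(tree$nodes, v)
    tree <- add_edge(tree, u, w, newlen)
  }
  as_weighted_tree(tree)
}

switching_space_size <- function(net) {
  rets <- reticulation_nodes(net)
  prod(c(1, vapply(rets, function(v) length(edge_ids_in(net, v)), 1L),
         vapply(net$lengths, length, 1L)))
}

#' Enumerate the trees displayed by a network
#'
#' Runs over all switchings (one in-edge per reticulation, one length per
#' edge), suppresses each contained tree, and deduplicates the results up to
#' isomorphism via canonical codes. Enumeration order is deterministic
#' (reticulations in sorted node order), so the result is reproducible.
#'
#' @param net a valid `phylo_network`.
#' @param cap refuse to enumerate more than this many switchings
#'   (default 1e6); the bound is the product of reticulation indegrees and
#'   length-set sizes.
#' @return named list of `phylo_tree` objects; names are canonical codes.
#' @export
displayed_trees <- function(net, cap = 1e6) {
  if (switching_space_size(net) > cap)
    stop("switching space exceeds enumeration cap (", cap,
         "); raise `cap` to proceed", call. = FALSE)
  rets <- reticulation_nodes(net)
  in_lists <- lapply(rets, function(v) edge_ids_in(net, v))
  combos <- if (length(rets)) do.call(expand.grid, in_lists) else
    data.frame(row.names = 1)
  out <- list()
  for (r in seq_len(nrow(combos))) {
    ret_edges <- if (length(rets))
      stats::setNames(as.integer(combos[r, ]), rets) else
      stats::setNames(integer(0), character(0))
    s0 <- switching(ret_edges)
    skel <- contained_tree(net, s0)
    # length choices only matter on edges retained in the skeleton
    ekey <- paste(skel$from, skel$to, sep = "\r")
    nkey <- paste(net$from, net$to, sep = "\r")
    retained <- match(ekey, nkey)
    sizes <- vapply(net$lengths[retained], length, 1L)
    multi <- which(sizes > 1L)
    lc_grid <- if (length(multi))
      do.call(expand.grid, lapply(sizes[multi], seq_len)) else
      data.frame(row.names = 1)
    for (q in seq_len(nrow(lc_grid))) {
      tr <- skel
      if (length(multi)) {
        pick <- as.integer(lc_grid[q, ])
        for (j in seq_along(multi))
          tr$lengths[[multi[j]]] <-
            net$lengths[[retained[multi[j]]]][pick[j]]
      }
      tr2 <- suppress_all(as_weighted_tree(tr))
      code <- tree_canonical_code(tr2)
      if (is.null(out[[code]])) out[[code]] <- tr2
    }
  }
  out
}

#' Does a network display a given weighted tree?
#'
#' Membership of `tree` in the displayed-tree set of `net`, up to
#' isomorphism. A taxon-set mismatch yields `FALSE` with a warning.
#'
#' @param net a valid `phylo_network`.
#' @param tree a `phylo_tree` (suppressible nodes are suppressed first).
#' @param cap see [displayed_trees()].
#' @return logical flag.
#' @export
displays <- function(net, tree, cap = 1e6) {
  if (!setequal(net_taxa(net), net_taxa(tree))) {
    warning("taxon sets differ; the tree cannot be displayed")
    return(FALSE)
  }
  code <- tree_canonical_code(suppress_all(tree))
  code %in% names(displayed_trees(net, cap = cap))
}

#' Indistinguishability of two networks
#'
#' Two networks are indistinguishable when they display exactly the same set
#' of weighted trees; no inference criterion that scores a network through
#' its displayed trees can separate them. `mode = "direct"` compares the
#' enumerated displayed-tree sets. `mode = "canonical"` compares canonical
#' forms instead, which is valid only under the no-equally-long-paths (NELP)
#' property — the hypothesis under which canonical forms are unique — and is
#' refused otherwise with a suggestion to use direct mode.
#'
#' @param n1,n2 valid `phylo_network` objects on the same taxa.
#' @param mode `"direct"` or `"canonical"`.
#' @param cap see [displayed_trees()].
#' @return logical flag.
#' @export
indistinguishable <- function(n1, n2, mode = c("direct", "canonical"),
                              cap = 1e6) {
  mode <- match.arg(mode)
  if (!setequal(net_taxa(n1), net_taxa(n2))) return(FALSE)
  if (mode == "direct") {
    setequal(names(displayed_trees(n1, cap = cap)),
             names(displayed_trees(n2, cap = cap)))
  } else {
    if (!check_nelp(n1)$nelp || !check_nelp(n2)$nelp)
      stop("canonical-mode comparison requires both networks to satisfy the ",
           "NELP property (canonical forms are only unique under NELP); ",
           "use mode = \"direct\"", call. = FALSE)
    are_isomorphic(canonicalize(n1)$network, canonicalize(n2)$network)
  }
}
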