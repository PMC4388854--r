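# Reduction to canonical form.
#
# Two local rewrite rules drive the reduction:
#   R1 (funnel suppression): a funnel v with in-edges (u_i, v) and out-edge
#      (v, w) is removed; each u_i is joined directly to w with the Minkowski
#      set-sum of lengths, Λ(u_i, w) = Λ(u_i, v) + Λ(v, w).
#   R2 (multiedge merging): parallel edges u -> w are replaced by one edge
#      whose length set is the union of theirs.
# Applying the rules until neither fires yields a funnel-free, multiedge-free
# network displaying exactly the same weighted trees; under the NELP property
# this canonical form is unique up to isomorphism and the order of rule
# application does not matter. Multiedges are permitted only transiently
# inside the reduction.

#' Funnel suppression (rule R1)
#'
#' @param net a valid `phylo_network` (multiedges tolerated transiently).
#' @param v a funnel node of `net`.
#' @return the rewritten network, with `multiedge_mode` on if parallel edges
#'   were produced (they are flagged for [apply_r2()]).
#' @export
apply_r1 <- function(net, v) {
  ind <- net_indegree(net); outd <- net_outdegree(net)
  if (!(v %in% net$nodes) || ind[v] < 1L || outd[v] != 1L)
    stop("node ", v, " is not a funnel", call. = FALSE)
  e_out <- edge_ids_out(net, v)
  w <- net$to[e_out]
  out_len <- net$lengths[[e_out]]
  e_in <- edge_ids_in(net, v)
  us <- net$from[e_in]
  in_lens <- net$lengths[e_in]
  net <- drop_edges(net, c(e_in, e_out))
  net$nodes <- setdiff(net$nodes, v)
  for (j in seq_along(us))
    net <- add_edge(net, us[j], w, ls_sum(in_lens[[j]], out_len))
  key <- paste(net$from, net$to, sep = "\r")
  net$multiedge_mode <- anyDuplicated(key) > 0L
  net
}

#' Multiedge merging (rule R2)
#'
#' @param net a network in `multiedge_mode`.
#' @param u,w endpoints carrying at least two parallel edges.
#' @return the rewritten network (simple again if no other multiedge remains).
#' @export
apply_r2 <- function(net, u, w) {
  ids <- which(net$from == u & net$to == w)
  if (length(ids) < 2L)
    stop("no multiedge at (", u, ", ", w, ")", call. = FALSE)
  merged <- Reduce(ls_union, net$lengths[ids])
  net <- drop_edges(net, ids)
  net <- add_edge(net, u, w, merged)
  key <- paste(net$from, net$to, sep = "\r")
  net$multiedge_mode <- anyDuplicated(key) > 0L
  net
}

find_multiedge <- function(net) {
  key <- paste(net$from, net$to, sep = "\r")
  dup <- key[duplicated(key)]
  if (!length(dup)) return(NULL)
  strsplit(sort(dup)[1], "\r", fixed = TRUE)[[1]]
}

#' Reduce a network to its canonical form
#'
#' Repeatedly applies [apply_r2()] (eagerly, whenever a multiedge exists) and
#' [apply_r1()] (to the lexicographically first funnel) until neither rule
#' fires. The output is funnel-free and multiedge-free and displays exactly
#' the same weighted trees as the input; each step removes at least one edge,
#' so at most as many steps run as there are edges. The end result does not
#' depend on the order of rule application; `order = "random"` applies the
#' rules in a seeded random order and exists to let tests confirm that
#' confluence.
#'
#' @param net a valid `phylo_network`.
#' @param order `"deterministic"` (default) or `"random"`.
#' @param seed integer seed used when `order = "random"`.
#' @return a list with elements `network` (the canonical form) and `trace`
#'   (class `reduction_trace`): one row per step with the rule name, the
#'   affected node or edge, and the before/after length sets.
#' @export
canonicalize <- function(net, order = c("deterministic", "random"),
                         seed = NULL) {
  order <- match.arg(order)
  if (order == "random" && !is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  steps <- list()
  repeat {
    me <- find_multiedge(net)
    funnels <- funnel_nodes(net)
    if (order == "random") {
      # choose uniformly among all currently applicable rule instances
      keys <- paste(net$from, net$to, sep = "\r")
      mes <- unique(keys[duplicated(keys)])
      cand <- c(if (length(mes)) paste0("R2\r", mes),
                if (length(funnels)) paste0("R1\r", funnels))
      if (!length(cand)) break
      pick <- strsplit(sample(cand, 1), "\r", fixed = TRUE)[[1]]
      if (pick[1] == "R2") {
        me <- c(pick[2], pick[3]); funnels <- character(0)
      } else { me <- NULL; funnels <- pick[2] }
    }
    if (!is.null(me)) {
      ids <- which(net$from == me[1] & net$to == me[2])
      before <- vapply(net$lengths[ids], ls_key, character(1))
      net <- apply_r2(net, me[1], me[2])
      after <- ls_key(net$lengths[[which(net$from == me[1] & net$to == me[2])]])
      steps[[length(steps) + 1L]] <-
        list(rule = "R2", target = paste0(me[1], "->", me[2]),
             before = paste(before, collapse = " "), after = after)
    } else if (length(funnels)) {
      v <- funnels[1]
      e_out <- edge_ids_out(net, v); e_in <- edge_ids_in(net, v)
      before <- paste(c(vapply(net$lengths[e_in], ls_key, character(1)),
                        ls_key(net$lengths[[e_out]])), collapse = " ")
      us <- net$from[e_in]; w <- net$to[e_out]
      net <- apply_r1(net, v)
      after <- paste(vapply(seq_along(us), function(j) {
        ids <- which(net$from == us[j] & net$to == w)
        paste(vapply(net$lengths[ids], ls_key, character(1)), collapse = "+")
      }, character(1)), collapse = " ")
      steps[[length(steps) + 1L]] <-
        list(rule = "R1", target = v, before = before, after = after)
    } else break
  }
  net$multiedge_mode <- FALSE
  trace <- do.call(rbind, lapply(steps, as.data.frame))
  if (is.null(trace))
    trace <- data.frame(rule = character(0), target = character(0),
                        before = character(0), after = character(0))
  class(trace) <- c("reduction_trace", class(trace))
  list(network = net, trace = trace)
}

#' Unzip a reticulation
#'
#' For a reticulation `v` with outdegree 1 the length of the out-edge is not
#' identifiable: shifting `delta` from the out-edge onto every in-edge leaves
#' the displayed trees unchanged. When `delta` equals the whole out-edge
#' length, `v` merges with its child. Defined only where the touched edges
#' carry single lengths.
#'
#' @param net a valid `phylo_network`.
#' @param v a reticulation with outdegree 1.
#' @param delta positive length (coerced with [as_rational()]), at most the
#'   out-edge length.
#' @return the rewritten network.
#' @export
unzip <- function(net, v, delta) {
  delta <- as_rational(delta)
  ind <- net_indegree(net); outd <- net_outdegree(net)
  if (!(v %in% net$nodes) || ind[v] < 2L || outd[v] != 1L)
    stop("unzip requires a reticulation with outdegree 1", call. = FALSE)
  e_out <- edge_ids_out(net, v); e_in <- edge_ids_in(net, v)
  if (any(vapply(net$lengths[c(e_in, e_out)], length, 1L) > 1L))
    stop("unzip is defined only on single-valued length sets", call. = FALSE)
  out_len <- net$lengths[[e_out]]
  if (delta$num <= 0 || rat_cmp(delta, out_len) > 0)
    stop("delta must satisfy 0 < delta <= out-edge length", call. = FALSE)
  for (i in e_in) net$lengths[[i]] <- ls_shift(net$lengths[[i]], delta)
  if (rat_eq(delta, out_len)) {
    w <- net$to[e_out]
    us <- net$from[e_in]
    lens <- net$lengths[e_in]
    net <- drop_edges(net, c(e_in, e_out))
    net$nodes <- setdiff(net$nodes, v)
    for (j in seq_along(us)) {
      dup <- which(net$from == us[j] & net$to == w)
      if (length(dup)) {
        net$lengths[[dup]] <- ls_union(net$lengths[[dup]], lens[[j]])
      } else {
        net <- add_edge(net, us[j], w, lens[[j]])
      }
    }
  } else {
    net$lengths[[e_out]] <- ls_shift(out_len, delta, sign = -1)
  }
  net
}

#' Insert a funnel above a node (inverse of R1)
#'
#' Splits off `delta` from the bottom of the chosen in-edges of `w`,
#' rerouting them through a new funnel node `v` joined to `w` by an edge of
#' length `delta`. Canonicalizing the result recovers the canonical form of
#' the input, which makes this the engine for generating indistinguishable
#' network families.
#'
#' @param net a valid `phylo_network`.
#' @param w target node (indegree at least 1).
#' @param in_edges edge indices of the in-edges of `w` to reroute.
#' @param delta positive length strictly below every length value on the
#'   chosen in-edges.
#' @return the rewritten network containing one extra (funnel) node.
#' @export
zip_insert_funnel <- function(net, w, in_edges, delta) {
  delta <- as_rational(delta)
  if (delta$num <= 0) stop("delta must be positive", call. = FALSE)
  if (!length(in_edges) || !all(in_edges %in% edge_ids_in(net, w)))
    stop("in_edges must be in-edges of ", w, call. = FALSE)
  for (i in in_edges) {
    l <- net$lengths[[i]]
    if (any(rat_cmp(l, delta) <= 0))
      stop("delta must be strictly below every affected length value",
           call. = FALSE)
  }
  v <- fresh_node_id(net, "z")
  net$nodes <- c(net$nodes, v)
  for (i in in_edges) {
    net$to[i] <- v
    net$lengths[[i]] <- ls_shift(net$lengths[[i]], delta, sign = -1)
  }
  # merge any parallel edges into v created by rerouting two edges from the
  # same parent
  key <- paste(net$from, net$to, sep = "\r")
  while (anyDuplicated(key)) {
    dup <- strsplit(key[duplicated(key)][1], "\r", fixed = TRUE)[[1]]
    ids <- which(net$from == dup[1] & net$to == dup[2])
    merged <- Reduce(ls_union, net$lengths[ids])
    net <- drop_edges(net, ids)
    net <- add_edge(net, dup[1], dup[2], merged)
    key <- paste(net$from, net$to, sep = "\r")
  }
  add_edge(net, v, w, lengthset(delta))
}
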