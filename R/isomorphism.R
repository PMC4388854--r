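# Isomorphism of leaf-labeled rooted DAGs with length sets.
#
# Two devices are combined. A canonical code (memoized bottom-up expansion of
# each node into a sorted bracket string) is a fast invariant: isomorphic
# networks always get equal codes. Because bottom-up codes alone are not a
# complete invariant for DAGs — distinct nodes can share identical descendant
# structure — equality claims are always confirmed by an explicit backtracking
# bijection search, and a permutation-exhaustive oracle is provided for
# testing the pair.

node_codes <- function(net) {
  ord <- topo_order(net)
  code <- stats::setNames(character(length(net$nodes)), net$nodes)
  for (v in rev(ord)) {
    out <- edge_ids_out(net, v)
    if (!length(out)) {
      code[v] <- paste0("'", v, "'")
    } else {
      parts <- sort(paste0(vapply(net$lengths[out], ls_key, character(1)),
                           ">", code[net$to[out]]))
      code[v] <- paste0("(", paste(parts, collapse = ","), ")")
    }
  }
  code
}

#' Canonical code of a network
#'
#' A deterministic text form, identical for isomorphic networks: invariant
#' under renaming of internal node identifiers and permutation of child
#' order. It embeds leaf labels and exact length-set values. The code is a
#' complete invariant for weighted trees; for general networks it is a strong
#' invariant that [are_isomorphic()] backs with an explicit bijection search.
#'
#' @param net a valid `phylo_network` with `multiedge_mode` off.
#' @return a single character string.
#' @export
network_canonical_code <- function(net) {
  if (net$multiedge_mode && anyDuplicated(paste(net$from, net$to)))
    stop("canonical codes are undefined for multiedge networks; normalize first",
         call. = FALSE)
  codes <- node_codes(net)
  ind <- net_indegree(net)
  degs <- sort(paste0(ind, ":", net_outdegree(net)))
  paste0("V", length(net$nodes), "E", n_edges(net),
         "D[", paste(degs, collapse = ","), "]",
         "R[", paste(sort(codes[ind > 1L]), collapse = "|"), "]",
         codes[net_root(net)])
}

#' @rdname network_canonical_code
#' @export
tree_canonical_code <- function(tree) network_canonical_code(tree)

edge_key_map <- function(net) {
  stats::setNames(vapply(net$lengths, ls_key, character(1)),
                  paste(net$from, net$to, sep = "\r"))
}

mapping_is_isomorphism <- function(n1, n2, map) {
  # map: named character, names = n1 nodes, values = n2 nodes
  k1 <- paste(map[n1$from], map[n1$to], sep = "\r")
  k2 <- paste(n2$from, n2$to, sep = "\r")
  if (length(k1) != length(k2)) return(FALSE)
  o1 <- order(k1); o2 <- order(k2)
  if (!identical(k1[o1], k2[o2])) return(FALSE)
  l1 <- vapply(n1$lengths, ls_key, character(1))[o1]
  l2 <- vapply(n2$lengths, ls_key, character(1))[o2]
  identical(l1, l2)
}

iso_backtrack <- function(n1, n2) {
  leaves1 <- net_leaves(n1); leaves2 <- net_leaves(n2)
  if (!setequal(leaves1, leaves2)) return(FALSE)
  int1 <- setdiff(n1$nodes, leaves1)
  int2 <- setdiff(n2$nodes, leaves2)
  if (length(int1) != length(int2)) return(FALSE)
  c1 <- node_codes(n1); c2 <- node_codes(n2)
  ind1 <- net_indegree(n1); ind2 <- net_indegree(n2)
  out1 <- net_outdegree(n1); out2 <- net_outdegree(n2)
  sig1 <- paste0(c1, "#", ind1[names(c1)], "#", out1[names(c1)])
  sig2 <- paste0(c2, "#", ind2[names(c2)], "#", out2[names(c2)])
  names(sig1) <- names(c1); names(sig2) <- names(c2)
  if (!identical(sort(unname(sig1[int1])), sort(unname(sig2[int2]))))
    return(FALSE)
  ekey2 <- edge_key_map(n2)
  # order n1's internal nodes: most-constrained (rarest signature) first
  tab <- table(sig1[int1])
  int1 <- int1[order(tab[sig1[int1]], int1)]
  map <- stats::setNames(leaves1, leaves1)
  used <- character(0)
  edges1_by_node <- lapply(stats::setNames(n1$nodes, n1$nodes), function(v)
    list(out = edge_ids_out(n1, v), inn = edge_ids_in(n1, v)))
  lkey1 <- vapply(n1$lengths, ls_key, character(1))

  consistent <- function(v, w, map) {
    # every n1-edge incident to v whose other endpoint is already mapped must
    # exist in n2 with the same length set
    e <- edges1_by_node[[v]]
    for (i in e$out) {
      t <- n1$to[i]
      tm <- if (t == v) w else map[t]
      if (!is.na(tm)) {
        k <- paste(w, tm, sep = "\r")
        if (is.na(ekey2[k]) || ekey2[k] != lkey1[i]) return(FALSE)
      }
    }
    for (i in e$inn) {
      s <- n1$from[i]
      sm <- if (s == v) w else map[s]
      if (!is.na(sm)) {
        k <- paste(sm, w, sep = "\r")
        if (is.na(ekey2[k]) || ekey2[k] != lkey1[i]) return(FALSE)
      }
    }
    TRUE
  }

  rec <- function(idx, map, used) {
    if (idx > length(int1)) return(mapping_is_isomorphism(n1, n2, map))
    v <- int1[idx]
    cand <- setdiff(int2[sig2[int2] == sig1[v]], used)
    for (w in cand) {
      map2 <- map; map2[v] <- w
      if (consistent(v, w, map2) && rec(idx + 1L, map2, c(used, w)))
        return(TRUE)
    }
    FALSE
  }
  mapNA <- stats::setNames(rep(NA_character_, length(n1$nodes)), n1$nodes)
  mapNA[leaves1] <- leaves1
  rec(1L, mapNA, character(0))
}

#' Test whether two networks are isomorphic
#'
#' True when there is a graph bijection preserving directed edges, exact
#' length sets and leaf labels. Internal node identifiers carry no meaning.
#' Canonical-code equality serves as a fast pre-filter; a positive answer is
#' always confirmed by an explicit bijection search.
#'
#' @param n1,n2 valid `phylo_network` objects.
#' @return logical flag.
#' @export
are_isomorphic <- function(n1, n2) {
  if (!setequal(net_taxa(n1), net_taxa(n2))) return(FALSE)
  if (length(n1$nodes) != length(n2$nodes) || n_edges(n1) != n_edges(n2))
    return(FALSE)
  if (network_canonical_code(n1) != network_canonical_code(n2)) return(FALSE)
  iso_backtrack(n1, n2)
}

perms_mat <- function(n) {
  if (n == 0L) return(matrix(integer(0), nrow = 1))
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perms_mat(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Exhaustive isomorphism oracle
#'
#' Ground truth for testing [are_isomorphic()]: tries every bijection of
#' internal nodes that fixes the leaf labeling and checks edge and length-set
#' preservation directly. Refuses networks with more than `max_nodes` nodes.
#'
#' @param n1,n2 valid `phylo_network` objects.
#' @param max_nodes size guard (default 12).
#' @return logical flag.
#' @export
brute_force_isomorphic <- function(n1, n2, max_nodes = 12L) {
  if (length(n1$nodes) > max_nodes || length(n2$nodes) > max_nodes)
    stop("brute_force_isomorphic: size guard exceeded (", max_nodes,
         " nodes)", call. = FALSE)
  leaves1 <- net_leaves(n1); leaves2 <- net_leaves(n2)
  if (!setequal(leaves1, leaves2)) return(FALSE)
  if (length(n1$nodes) != length(n2$nodes) || n_edges(n1) != n_edges(n2))
    return(FALSE)
  int1 <- sort(setdiff(n1$nodes, leaves1))
  int2 <- sort(setdiff(n2$nodes, leaves2))
  if (length(int1) != length(int2)) return(FALSE)
  if (length(int1) == 0L) {
    map <- stats::setNames(leaves1, leaves1)
    return(mapping_is_isomorphism(n1, n2, map))
  }
  P <- perms_mat(length(int1))
  base <- stats::setNames(c(leaves1, rep(NA_character_, length(int1))),
                          c(leaves1, int1))
  for (r in seq_len(nrow(P))) {
    map <- base
    map[int1] <- int2[P[r, ]]
    if (mapping_is_isomorphism(n1, n2, map)) return(TRUE)
  }
  FALSE
}
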