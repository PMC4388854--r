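# Core data model: weighted rooted phylogenetic networks.
#
# A network is a rooted DAG whose leaves are bijectively labeled with taxa and
# whose edges each carry a finite set of positive lengths. By convention the
# identifier of a leaf node IS its taxon label; internal identifiers are
# opaque and irrelevant for isomorphism.

#' Construct a weighted rooted phylogenetic network
#'
#' @param edges two-column character matrix or data frame of directed edges
#'   (parent, child). May have zero rows for a single-leaf network.
#' @param lengths list with one entry per edge; each entry is coerced with
#'   [lengthset()] (so numeric vectors, exact-decimal strings and `rational`s
#'   are accepted).
#' @param nodes optional character vector of node identifiers; defaults to the
#'   nodes appearing in `edges`. Needed for the edgeless single-node network.
#' @param multiedge_mode if `TRUE`, parallel edges with identical endpoints
#'   are tolerated (used transiently inside the reduction algorithm; public
#'   outputs are always simple).
#' @param validate check invariants and stop on violation (default `TRUE`).
#' @return an object of class `phylo_network`.
#' @seealso [validate_network()], [parse_network()]
#' @export
phylo_network <- function(edges, lengths = NULL, nodes = NULL,
                          multiedge_mode = FALSE, validate = TRUE) {
  if (is.null(edges) || NROW(edges) == 0L) {
    from <- character(0); to <- character(0)
  } else {
    edges <- as.matrix(edges)
    from <- as.character(edges[, 1]); to <- as.character(edges[, 2])
  }
  if (is.null(lengths)) lengths <- rep(list(1), length(from))
  if (length(lengths) != length(from))
    stop("need exactly one length set per edge", call. = FALSE)
  lengths <- lapply(lengths, function(l)
    if (inherits(l, "lengthset")) l else lengthset(l))
  if (is.null(nodes)) nodes <- unique(c(from, to))
  nodes <- unique(as.character(nodes))
  net <- structure(list(nodes = nodes, from = from, to = to,
                        lengths = lengths, multiedge_mode = multiedge_mode),
                   class = "phylo_network")
  if (validate) {
    bad <- validate_network(net)
    if (length(bad))
      stop("invalid network: ", paste(bad, collapse = "; "), call. = FALSE)
  }
  net
}

n_edges <- function(net) length(net$from)

net_indegree <- function(net) {
  d <- stats::setNames(integer(length(net$nodes)), net$nodes)
  t <- table(net$to); d[names(t)] <- as.integer(t)
  d
}

net_outdegree <- function(net) {
  d <- stats::setNames(integer(length(net$nodes)), net$nodes)
  t <- table(net$from); d[names(t)] <- as.integer(t)
  d
}

#' Network root, leaves and taxa
#'
#' The root is the unique indegree-0 node; the leaves are the outdegree-0
#' nodes and their identifiers are the taxon labels.
#'
#' @param net a `phylo_network`.
#' @return `net_root`: a node id; `net_leaves` / `net_taxa`: character vector.
#' @export
net_root <- function(net) {
  r <- net$nodes[net_indegree(net) == 0L]
  if (length(r) != 1L) stop("network has no unique root", call. = FALSE)
  r
}

#' @rdname net_root
#' @export
net_leaves <- function(net) net$nodes[net_outdegree(net) == 0L]

#' @rdname net_root
#' @export
net_taxa <- function(net) sort(net_leaves(net))

net_children <- function(net, v) net$to[net$from == v]
net_parents <- function(net, v) net$from[net$to == v]
edge_ids_out <- function(net, v) which(net$from == v)
edge_ids_in <- function(net, v) which(net$to == v)

net_is_acyclic <- function(net) {
  n <- length(net$nodes)
  indeg <- net_indegree(net)
  queue <- net$nodes[indeg == 0L]
  seen <- 0L
  indeg2 <- indeg
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (w in net_children(net, v)) {
      indeg2[w] <- indeg2[w] - 1L
      if (indeg2[w] == 0L) queue <- c(queue, w)
    }
  }
  seen == n
}

topo_order <- function(net) {
  indeg <- net_indegree(net)
  queue <- sort(net$nodes[indeg == 0L])
  out <- character(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (w in net_children(net, v)) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- sort(c(queue, w))
    }
  }
  out
}

#' Validate network invariants
#'
#' Checks the defining invariants of a weighted rooted phylogenetic network
#' and reports every violation rather than stopping at the first: acyclicity,
#' a unique root, positivity and non-emptiness of every length set, absence
#' of parallel edges (unless `multiedge_mode` is on), and no dangling edge
#' endpoints.
#'
#' @param net a `phylo_network` (possibly malformed).
#' @return character vector of human-readable violations; empty when valid.
#' @export
validate_network <- function(net) {
  bad <- character(0)
  ep <- unique(c(net$from, net$to))
  if (!all(ep %in% net$nodes))
    bad <- c(bad, paste0("edge endpoint not a declared node: ",
                         paste(setdiff(ep, net$nodes), collapse = ",")))
  if (length(net$nodes) == 0L) return(c(bad, "empty node set"))
  if (any(net$from == net$to))
    bad <- c(bad, "self-loop edge")
  roots <- net$nodes[net_indegree(net) == 0L]
  if (length(roots) == 0L) bad <- c(bad, "not rooted: no indegree-0 node")
  if (length(roots) > 1L)
    bad <- c(bad, paste0("not rooted: multiple indegree-0 nodes (",
                         paste(sort(roots), collapse = ","), ")"))
  if (!net_is_acyclic(net)) bad <- c(bad, "cyclic")
  if (!net$multiedge_mode) {
    key <- paste(net$from, net$to, sep = "\r")
    dup <- unique(key[duplicated(key)])
    if (length(dup))
      bad <- c(bad, paste0("parallel edges at ",
                           paste(gsub("\r", "->", dup), collapse = ",")))
  }
  for (i in seq_along(net$lengths)) {
    l <- net$lengths[[i]]
    if (!inherits(l, "lengthset") || length(l) == 0L || any(l$num <= 0)) {
      bad <- c(bad, paste0("invalid length set on edge ", net$from[i], "->",
                           net$to[i]))
    }
  }
  lv <- net$nodes[net_outdegree(net) == 0L]
  if (length(roots) == 1L && length(lv) == 1L && lv == roots &&
      length(net$nodes) > 1L)
    bad <- c(bad, "root is the only leaf in a multi-node graph")
  if (anyDuplicated(lv)) bad <- c(bad, "duplicate leaf label")
  bad
}

#' Reticulation nodes
#'
#' A reticulation is a node with indegree greater than 1: a lineage that
#' inherits genetic material from more than one direct ancestor
#' (hybridisation, horizontal transfer, recombination).
#'
#' @param net a valid `phylo_network`.
#' @return character vector of node ids (possibly empty), sorted.
#' @export
reticulation_nodes <- function(net) {
  sort(net$nodes[net_indegree(net) > 1L])
}

#' Funnel nodes
#'
#' A funnel is a node with indegree at least 1 and outdegree exactly 1. A
#' network with no funnels is in canonical form. Suppressible tree nodes
#' (indegree 1, outdegree 1) are a special case of funnels.
#'
#' @param net a valid `phylo_network`.
#' @return character vector of node ids (possibly empty), sorted.
#' @export
funnel_nodes <- function(net) {
  ind <- net_indegree(net); outd <- net_outdegree(net)
  sort(net$nodes[ind >= 1L & outd == 1L])
}

#' @rdname funnel_nodes
#' @export
is_funnel_free <- function(net) length(funnel_nodes(net)) == 0L

#' Weighted trees
#'
#' A weighted phylogenetic tree is a network with no reticulations in which
#' every edge carries exactly one length. `as_weighted_tree` checks those
#' conditions and stamps the subclass; `is_weighted_tree` only tests them.
#' Suppressible (indegree-1/outdegree-1) nodes are permitted here because
#' intermediate "contained" trees carry them; displayed trees never do.
#'
#' @param net a `phylo_network`.
#' @return `as_weighted_tree`: the same object with class `phylo_tree`
#'   prepended; `is_weighted_tree`: a logical flag.
#' @export
as_weighted_tree <- function(net) {
  if (!is_weighted_tree(net))
    stop("not a weighted tree: has reticulations or multi-valued lengths",
         call. = FALSE)
  class(net) <- unique(c("phylo_tree", class(net)))
  net
}

#' @rdname as_weighted_tree
#' @export
is_weighted_tree <- function(net) {
  all(net_indegree(net) <= 1L) &&
    all(vapply(net$lengths, length, 1L) == 1L)
}

edge_length_value <- function(net, i) {
  l <- net$lengths[[i]]
  if (length(l) != 1L) stop("edge has multiple lengths", call. = FALSE)
  l
}

drop_edges <- function(net, ids) {
  if (!length(ids)) return(net)
  net$from <- net$from[-ids]; net$to <- net$to[-ids]
  net$lengths <- net$lengths[-ids]
  net
}

drop_nodes <- function(net, vs) {
  keep <- !(net$from %in% vs | net$to %in% vs)
  net$from <- net$from[keep]; net$to <- net$to[keep]
  net$lengths <- net$lengths[keep]
  net$nodes <- setdiff(net$nodes, vs)
  net
}

add_edge <- function(net, u, w, lens) {
  net$from <- c(net$from, u); net$to <- c(net$to, w)
  net$lengths <- c(net$lengths, list(lens))
  if (!(u %in% net$nodes)) net$nodes <- c(net$nodes, u)
  if (!(w %in% net$nodes)) net$nodes <- c(net$nodes, w)
  net
}

fresh_node_id <- function(net, prefix = "n") {
  i <- length(net$nodes) + 1L
  repeat {
    id <- paste0(".", prefix, i)
    if (!(id %in% net$nodes)) return(id)
    i <- i + 1L
  }
}

#' @export
print.phylo_network <- function(x, ...) {
  kind <- if (inherits(x, "phylo_tree")) "weighted tree" else "network"
  cat(sprintf("<%s> %d nodes, %d edges, %d taxa", kind, length(x$nodes),
              n_edges(x), length(net_leaves(x))))
  rets <- sum(net_indegree(x) > 1L)
  if (rets) cat(sprintf(", %d reticulation%s", rets, if (rets > 1) "s" else ""))
  cat("\n")
  if (n_edges(x) <= 30L) {
    for (i in seq_len(n_edges(x)))
      cat("  ", x$from[i], " -> ", x$to[i], " ",
          ls_key(x$lengths[[i]]), "\n", sep = "")
  }
  invisible(x)
}
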