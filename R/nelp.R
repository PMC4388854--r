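# Weighted paths, the NELP property, wishbones and cracks.
#
# A weighted path is a directed path together with a choice of one length
# per edge; two weighted paths are distinct if they differ in either the
# underlying path or the length choice. A network satisfies NELP ("no
# equally long paths") when no two distinct weighted paths with the same
# endpoints have the same total length. NELP is generic when lengths measure
# divergence (continuous draws collide with probability zero) but fails
# systematically under a strict clock, where all paths to a node are equally
# long by construction.

weighted_path <- function(nodes, edges, lengths) {
  total <- if (length(lengths)) rat_sum(lengths) else rational(0, 1)
  structure(list(nodes = nodes, edges = edges, lengths = lengths,
                 total = total),
            class = "weighted_path")
}

#' @export
print.weighted_path <- function(x, ...) {
  cat("<weighted_path> ", paste(x$nodes, collapse = " -> "),
      "  lengths: ", if (length(x$lengths)) paste(rat_format(x$lengths), collapse = ","),
      "  total: ", rat_format(x$total), "\n", sep = "")
  invisible(x)
}

path_signature <- function(p)
  paste(paste(p$nodes, collapse = ">"),
        if (length(p$lengths)) paste(rat_format(p$lengths), collapse = ","),
        sep = "|")

#' Enumerate weighted paths between two nodes
#'
#' All distinct weighted paths from `u` to `v`, including distinct length
#' choices over the same underlying path. The single trivial (edge-free)
#' path is returned when `u == v`. Order is deterministic: depth-first with
#' children in sorted order, length values ascending.
#'
#' @param net a valid `phylo_network`.
#' @param u,v node identifiers.
#' @param cap refuse to enumerate more than this many weighted paths
#'   (default 1e5); the failure is explicit, never a silent truncation.
#' @return list of `weighted_path` objects.
#' @export
weighted_paths_between <- function(net, u, v, cap = 1e5) {
  stopifnot(u %in% net$nodes, v %in% net$nodes)
  out <- list()
  rec <- function(node, eidx, lens) {
    if (node == v) {
      if (length(out) + 1L > cap)
        stop("weighted-path enumeration cap (", cap, ") exceeded", call. = FALSE)
      nodes <- c(u, net$to[eidx])
      out[[length(out) + 1L]] <<- weighted_path(nodes, eidx,
        if (length(lens)) do.call(c.rational, lens) else rational(numeric(0)))
      return(invisible(NULL))
    }
    es <- edge_ids_out(net, node)
    es <- es[order(net$to[es])]
    for (e in es) {
      l <- net$lengths[[e]]
      for (k in seq_len(length(l)))
        rec(net$to[e], c(eidx, e), c(lens, list(l[k])))
    }
  }
  rec(u, integer(0), list())
  out
}

#' Check the NELP property
#'
#' Scans every pair of nodes for two distinct weighted paths of identical
#' total length (compared exactly, as rationals). On violation the concrete
#' witness pair is returned.
#'
#' @param net a valid `phylo_network`.
#' @param cap per-source cap on enumerated weighted paths.
#' @return a list with `nelp` (logical) and `witness` (`NULL`, or a list of
#'   two `weighted_path` objects with equal endpoints and totals).
#' @export
check_nelp <- function(net, cap = 1e5) {
  ord <- topo_order(net)
  for (u in ord) {
    # enumerate all weighted paths out of u, grouped by endpoint
    seen <- new.env(parent = emptyenv())  # "endpoint|totalkey" -> path
    found <- NULL
    count <- 0L
    rec <- function(node, eidx, lens, total) {
      if (!is.null(found)) return(invisible(NULL))
      if (node != u) {
        count <<- count + 1L
        if (count > cap)
          stop("weighted-path enumeration cap (", cap, ") exceeded", call. = FALSE)
        key <- paste0(node, "|", rat_key(total))
        p <- weighted_path(c(u, net$to[eidx]), eidx,
          if (length(lens)) do.call(c.rational, lens) else rational(numeric(0)))
        prev <- seen[[key]]
        if (!is.null(prev)) {
          found <<- list(prev, p)
          return(invisible(NULL))
        }
        seen[[key]] <- p
      }
      es <- edge_ids_out(net, node)
      es <- es[order(net$to[es])]
      for (e in es) {
        l <- net$lengths[[e]]
        for (k in seq_len(length(l))) {
          rec(net$to[e], c(eidx, e), c(lens, list(l[k])), rat_add(total, l[k]))
          if (!is.null(found)) return(invisible(NULL))
        }
      }
    }
    rec(u, integer(0), list(), rational(0, 1))
    if (!is.null(found)) return(list(nelp = FALSE, witness = found))
  }
  list(nelp = TRUE, witness = NULL)
}

root_leaf_weighted_paths <- function(net, cap = 1e5) {
  r <- net_root(net)
  unlist(lapply(sort(net_leaves(net)), function(lf)
    weighted_paths_between(net, r, lf, cap = cap)), recursive = FALSE)
}

common_weighted_prefix_len <- function(p1, p2) {
  # number of shared leading nodes with identical edges and length choices
  n <- 1L  # the root is always shared
  k <- min(length(p1$edges), length(p2$edges))
  i <- 0L
  while (i < k &&
         p1$nodes[i + 2L] == p2$nodes[i + 2L] &&
         p1$edges[i + 1L] == p2$edges[i + 1L] &&
         rat_eq(p1$lengths[i + 1L], p2$lengths[i + 1L])) i <- i + 1L
  i + 1L  # nodes in the common prefix
}

common_weighted_suffix_len <- function(p1, p2) {
  n1 <- length(p1$nodes); n2 <- length(p2$nodes)
  if (p1$nodes[n1] != p2$nodes[n2]) return(0L)
  k <- min(n1, n2) - 1L
  i <- 0L
  while (i < k &&
         p1$nodes[n1 - i - 1L] == p2$nodes[n2 - i - 1L] &&
         p1$edges[length(p1$edges) - i] == p2$edges[length(p2$edges) - i] &&
         rat_eq(p1$lengths[length(p1$edges) - i],
                p2$lengths[length(p2$edges) - i])) i <- i + 1L
  i + 1L  # nodes in the common suffix
}

path_pair_union <- function(net, p1, p2) {
  # union sub-network of two root-leaf weighted paths; a shared edge used
  # with two different lengths receives both values
  ekey <- character(0); elens <- list(); efrom <- character(0); eto <- character(0)
  addp <- function(p) {
    for (j in seq_along(p$edges)) {
      e <- p$edges[j]
      k <- paste0(e)
      val <- p$lengths[j]
      pos <- match(k, ekey)
      if (is.na(pos)) {
        ekey <<- c(ekey, k); efrom <<- c(efrom, net$from[e])
        eto <<- c(eto, net$to[e]); elens <<- c(elens, list(val))
      } else {
        elens[[pos]] <<- c.rational(elens[[pos]], val)
      }
    }
  }
  addp(p1); addp(p2)
  lens <- lapply(elens, function(x) lengthset(x))
  phylo_network(cbind(efrom, eto), lens,
                nodes = unique(c(p1$nodes, p2$nodes)), validate = FALSE)
}

classify_path_pair <- function(p1, p2) {
  # returns "wishbone", "crack", "both" (identical paths), or NA
  if (path_signature(p1) == path_signature(p2)) return("both")
  shared <- intersect(p1$nodes, p2$nodes)
  pre <- common_weighted_prefix_len(p1, p2)
  pre_nodes <- p1$nodes[seq_len(pre)]
  suf <- common_weighted_suffix_len(p1, p2)
  suf_nodes <- if (suf > 0L)
    p1$nodes[seq(length(p1$nodes) - suf + 1L, length(p1$nodes))] else character(0)
  if (setequal(shared, pre_nodes)) return("wishbone")
  if (suf > 0L && setequal(shared, union(pre_nodes, suf_nodes)) &&
      !length(intersect(pre_nodes, suf_nodes))) return("crack")
  NA_character_
}

#' Enumerate wishbones and cracks
#'
#' A wishbone is the union of two root-leaf weighted paths that share only a
#' prefix; a crack is the union of two that share only a prefix and a
#' suffix. Every root-leaf path is degenerately both (the union of the path
#' with itself). A root-leaf path with two lengths attributed to one of its
#' edges arises here as the union of its two single-length versions and is a
#' crack. Results are deduplicated up to isomorphism.
#'
#' @param net a valid `phylo_network`.
#' @param cap cap on enumerated root-leaf weighted paths (default 2000;
#'   wishbone counts are quadratic in this number, hence the small default).
#' @return named list of sub-networks; names are canonical codes.
#' @export
enumerate_wishbones <- function(net, cap = 2000) {
  enumerate_path_unions(net, "wishbone", cap)
}

#' @rdname enumerate_wishbones
#' @export
enumerate_cracks <- function(net, cap = 2000) {
  enumerate_path_unions(net, "crack", cap)
}

enumerate_path_unions <- function(net, kind, cap) {
  paths <- root_leaf_weighted_paths(net, cap = cap)
  if (length(paths) > cap)
    stop("root-leaf path cap exceeded", call. = FALSE)
  out <- list()
  for (i in seq_along(paths)) {
    for (j in i:length(paths)) {
      cls <- classify_path_pair(paths[[i]], paths[[j]])
      if (is.na(cls)) next
      if (cls == kind || cls == "both") {
        u <- path_pair_union(net, paths[[i]], paths[[j]])
        code <- network_canonical_code(u)
        if (is.null(out[[code]])) out[[code]] <- u
      }
    }
  }
  out
}

#' Do two networks contain the same wishbones and cracks?
#'
#' Compares the two enumerations up to isomorphism. For networks with the
#' NELP property this holds if and only if the networks are isomorphic; it
#' also holds for indistinguishable funnel-free NELP networks. Without NELP
#' the equivalence can fail: non-isomorphic networks may share all wishbones
#' and cracks.
#'
#' @param n1,n2 valid `phylo_network` objects.
#' @param cap see [enumerate_wishbones()].
#' @return logical flag.
#' @export
same_wishbones_and_cracks <- function(n1, n2, cap = 2000) {
  setequal(names(enumerate_wishbones(n1, cap)), names(enumerate_wishbones(n2, cap))) &&
    setequal(names(enumerate_cracks(n1, cap)), names(enumerate_cracks(n2, cap)))
}
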