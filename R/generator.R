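# Synthetic network generation.
#
# All random lengths live on a fine rational grid (multiples of 1e-6), which
# plays the role of a continuous sampler — the probability that two distinct
# path sums coincide is ~1e-6 per pair, so generated networks satisfy NELP
# essentially always — while keeping every quantity exactly representable:
# grid rationals are closed under the set sums of the reduction rules and
# the shifts of zip/unzip, so no intermediate ever needs more precision.

.GRID <- 1e6

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  expr
}

#' Default branch-length sampler
#'
#' Draws lengths uniformly from the rational grid `{1/1e6, ..., 1}`.
#'
#' @param n number of draws.
#' @return a `rational` vector.
#' @export
grid_length_sampler <- function(n) rational(sample(.GRID, n, replace = TRUE), .GRID)

#' Generate a random weighted network
#'
#' Builds a random rooted binary tree on `n_taxa` leaves by successive
#' random joins, then adds `n_reticulations` reticulation events: each event
#' subdivides two distinct edges and joins the two new nodes by a fresh
#' edge, rejecting (and resampling) any placement that would create a
#' directed cycle. The subdivision points are funnels, as in biological
#' network drawings where a reticulation gives rise to a single lineage.
#'
#' @param n_taxa number of leaves (>= 1); taxa are named `t1, t2, ...`.
#' @param n_reticulations number of reticulation events (>= 0).
#' @param seed optional integer seed (local to this call).
#' @param length_sampler function(n) returning n lengths coercible by
#'   [lengthset()]; defaults to [grid_length_sampler()].
#' @return a valid `phylo_network`.
#' @export
random_network <- function(n_taxa, n_reticulations = 0L, seed = NULL,
                           length_sampler = grid_length_sampler) {
  stopifnot(n_taxa >= 1L, n_reticulations >= 0L)
  with_seed(seed, {
    taxa <- paste0("t", seq_len(n_taxa))
    nid <- 0L
    new_node <- function() { nid <<- nid + 1L; paste0("i", nid) }
    from <- character(0); to <- character(0); lens <- list()
    roots <- taxa
    while (length(roots) > 1L) {
      pick <- sample(length(roots), 2L)
      p <- new_node()
      l2 <- length_sampler(2L)
      from <- c(from, p, p); to <- c(to, roots[pick])
      lens <- c(lens, list(l2[1]), list(l2[2]))
      roots <- c(roots[-pick], p)
    }
    if (n_taxa == 1L) {
      p <- new_node()
      from <- p; to <- taxa; lens <- list(length_sampler(1L))
    }
    net <- phylo_network(cbind(from, to), lens)
    added <- 0L; tries <- 0L
    while (added < n_reticulations) {
      tries <- tries + 1L
      if (tries > 200L)
        stop("could not place requested reticulations without cycles",
             call. = FALSE)
      if (n_edges(net) < 2L)
        stop("network too small for a reticulation", call. = FALSE)
      es <- sample(n_edges(net), 2L)
      cand <- subdivide_and_link(net, es[1], es[2], length_sampler)
      if (!is.null(cand)) { net <- cand; added <- added + 1L }
    }
    net
  })
}

reachable_from <- function(net, v) {
  seen <- character(0); stack <- v
  while (length(stack)) {
    x <- stack[1]; stack <- stack[-1]
    if (x %in% seen) next
    seen <- c(seen, x)
    stack <- c(stack, net_children(net, x))
  }
  seen
}

subdivide_and_link <- function(net, e1, e2, length_sampler) {
  # subdivide e1 at p (reticulation source) and e2 at q (reticulation
  # target); build the candidate and test acyclicity directly
  p <- fresh_node_id(net, "p"); q <- fresh_node_id(net, "q")
  l <- length_sampler(5L)
  n2 <- net
  n2$to[e1] <- p
  n2 <- add_edge(n2, p, net$to[e1], lengthset(l[1]))
  n2$to[e2] <- q
  n2 <- add_edge(n2, q, net$to[e2], lengthset(l[2]))
  n2 <- add_edge(n2, p, q, lengthset(l[3]))
  if (!net_is_acyclic(n2)) return(NULL)
  if (length(validate_network(n2))) return(NULL)
  n2
}

#' Insert random funnels (zip moves)
#'
#' The engine for generating indistinguishable families: each of the `k`
#' moves splits a random amount off the bottom of a random subset of some
#' node's in-edges, routing them through a new funnel
#' ([zip_insert_funnel()]). The canonical form is unchanged, so two
#' differently-seeded funnelizations of the same network are always
#' indistinguishable, yet typically not isomorphic.
#'
#' @param net a valid `phylo_network`.
#' @param k number of funnels to insert (>= 1).
#' @param seed optional integer seed (local to this call).
#' @return a `phylo_network` with at least one funnel.
#' @export
random_funnelize <- function(net, k = 1L, seed = NULL) {
  stopifnot(k >= 1L)
  with_seed(seed, {
    for (rep in seq_len(k)) {
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (tries > 100L)
          stop("no feasible funnel-insertion site", call. = FALSE)
        w <- sample(setdiff(net$nodes, net_root(net)), 1L)
        ids <- edge_ids_in(net, w)
        ids <- ids[sample(length(ids))][seq_len(sample(length(ids), 1L))]
        # smallest affected length value, on the 1e-6 grid
        mins <- vapply(ids, function(i) {
          l <- net$lengths[[i]]
          min(l$num / l$den)
        }, 0)
        lo <- floor(min(mins) * .GRID)
        if (lo < 2) next
        delta <- rational(sample(lo - 1L, 1L), .GRID)
        net <- zip_insert_funnel(net, w, ids, delta)
        break
      }
    }
    net
  })
}

#' Generate a random alignment
#'
#' Uniform i.i.d. A/C/G/T sites: featureless data, sufficient for score
#' comparisons between networks (which hold for *any* alignment).
#'
#' @param taxa character vector of taxon names.
#' @param n_sites number of columns.
#' @param seed optional integer seed (local to this call).
#' @return an [alignment()].
#' @export
random_alignment <- function(taxa, n_sites = 20L, seed = NULL) {
  with_seed(seed, {
    alignment(stats::setNames(vapply(taxa, function(t)
      paste(sample(c("A", "C", "G", "T"), n_sites, replace = TRUE),
            collapse = ""), character(1)), taxa))
  })
}
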