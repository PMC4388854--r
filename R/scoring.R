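# Scores computed through displayed trees.
#
# These functions demonstrate why displayed trees drive identifiability:
# both the network parsimony score and the network likelihood are functions
# of the displayed-tree set (with, for likelihood, the tree probabilities
# induced by inheritance probabilities), so indistinguishable networks
# necessarily receive identical scores for every possible input alignment.

#' Construct an alignment
#'
#' @param x named character vector mapping taxon labels to equal-length
#'   character sequences.
#' @return object of class `alignment`.
#' @export
alignment <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("alignment sequences must be named by taxon", call. = FALSE)
  if (length(unique(nchar(x))) != 1L || nchar(x[1]) < 1L)
    stop("all sequences must have equal, positive length", call. = FALSE)
  structure(toupper(x), class = "alignment")
}

#' Read a FASTA alignment
#'
#' @param path FASTA file.
#' @return an [alignment()].
#' @export
read_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- vapply(as.character(dna), function(s)
    paste(toupper(s), collapse = ""), character(1))
  alignment(seqs)
}

aln_matrix <- function(aln) {
  do.call(rbind, lapply(unclass(aln), function(s) strsplit(s, "")[[1]]))
}

#' Small-parsimony score of a tree
#'
#' Minimum number of character changes needed on the tree to explain each
#' alignment column, summed over columns. Branch lengths are ignored.
#' Computed with Hartigan's bottom-up algorithm, which is exact for
#' arbitrary (multifurcating) rooted trees.
#'
#' @param tree a `phylo_tree` whose taxa match the alignment's.
#' @param aln an [alignment()].
#' @return non-negative integer.
#' @export
tree_parsimony <- function(tree, aln) {
  if (!setequal(net_taxa(tree), names(aln)))
    stop("alignment taxa do not match tree taxa", call. = FALSE)
  m <- aln_matrix(aln)
  ord <- rev(topo_order(tree))
  total <- 0L
  for (col in seq_len(ncol(m))) {
    states <- sort(unique(m[, col]))
    sets <- list()
    for (v in ord) {
      kids <- net_children(tree, v)
      if (!length(kids)) {
        sets[[v]] <- m[v, col]
      } else {
        cnt <- table(factor(unlist(sets[kids]), levels = states))
        K <- max(cnt)
        sets[[v]] <- states[cnt == K]
        total <- total + length(kids) - K
      }
    }
  }
  total
}

#' Network parsimony score
#'
#' For each alignment, the best small-parsimony score among all trees
#' displayed by the network; scores are summed over alignments (one
#' alignment per non-recombining region). Indistinguishable networks take
#' the minimum over the same tree set and therefore always score equally.
#'
#' @param net a valid `phylo_network`.
#' @param alignments a single [alignment()] or list of them.
#' @param cap see [displayed_trees()].
#' @return non-negative integer.
#' @export
network_parsimony <- function(net, alignments, cap = 1e6) {
  if (inherits(alignments, "alignment")) alignments <- list(alignments)
  trees <- displayed_trees(net, cap = cap)
  sum(vapply(alignments, function(a)
    min(vapply(trees, tree_parsimony, 0L, aln = a)), 0L))
}

.jc_pmat <- function(t) {
  e <- exp(-4 * t / 3)
  p_same <- 0.25 + 0.75 * e
  p_diff <- 0.25 - 0.25 * e
  m <- matrix(p_diff, 4, 4,
              dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  diag(m) <- p_same
  m
}

#' Likelihood of an alignment on a weighted tree (Jukes-Cantor)
#'
#' Felsenstein pruning under the equal-rates JC69 model with uniform root
#' distribution. Edge lengths are expected substitutions per site.
#' Characters outside A/C/G/T are treated as fully ambiguous.
#'
#' @param tree a `phylo_tree`.
#' @param aln an [alignment()] on the tree's taxa.
#' @return likelihood in (0, 1].
#' @export
tree_likelihood <- function(tree, aln) {
  if (!setequal(net_taxa(tree), names(aln)))
    stop("alignment taxa do not match tree taxa", call. = FALSE)
  m <- aln_matrix(aln)
  bases <- c("A", "C", "G", "T")
  ord <- rev(topo_order(tree))
  pmats <- lapply(seq_len(n_edges(tree)), function(i)
    .jc_pmat(rat_num(edge_length_value(tree, i))))
  lik <- 1
  for (col in seq_len(ncol(m))) {
    L <- list()
    for (v in ord) {
      out <- edge_ids_out(tree, v)
      if (!length(out)) {
        x <- rep(0, 4); names(x) <- bases
        ch <- m[v, col]
        if (ch %in% bases) x[ch] <- 1 else x[] <- 1
        L[[v]] <- x
      } else {
        x <- rep(1, 4)
        for (i in out) x <- x * as.vector(pmats[[i]] %*% L[[tree$to[i]]])
        L[[v]] <- x
      }
    }
    lik <- lik * sum(0.25 * L[[net_root(tree)]])
  }
  lik
}

#' Distribution over displayed trees induced by inheritance probabilities
#'
#' Each reticulation carries a probability for each of its in-edges (summing
#' to one); a structural switching occurs with the product of its chosen
#' probabilities, and the probability of a displayed tree is the sum over
#' the switchings that yield it.
#'
#' @param net a valid `phylo_network` with single-valued length sets.
#' @param inheritance_probs named numeric vector; names are `"u->v"` for
#'   every reticulation in-edge.
#' @return list with `trees` (named list of `phylo_tree`) and `prob` (named
#'   numeric, summing to 1); names are canonical codes.
#' @export
tree_distribution <- function(net, inheritance_probs) {
  if (any(vapply(net$lengths, length, 1L) > 1L))
    stop("likelihood machinery requires single-valued length sets; ",
         "multi-valued edges summarise several histories and have no single ",
         "tree probability", call. = FALSE)
  rets <- reticulation_nodes(net)
  ekey <- paste0(net$from, "->", net$to)
  for (v in rets) {
    ids <- edge_ids_in(net, v)
    p <- inheritance_probs[ekey[ids]]
    if (anyNA(p) || abs(sum(p) - 1) > 1e-9 || any(p < 0))
      stop("inheritance probabilities of the in-edges of ", v,
           " must be non-negative and sum to 1", call. = FALSE)
  }
  in_lists <- lapply(rets, function(v) edge_ids_in(net, v))
  combos <- if (length(rets)) do.call(expand.grid, in_lists) else
    data.frame(row.names = 1)
  trees <- list(); prob <- numeric(0)
  for (r in seq_len(nrow(combos))) {
    ret_edges <- if (length(rets))
      stats::setNames(as.integer(combos[r, ]), rets) else
      stats::setNames(integer(0), character(0))
    pr <- prod(c(1, inheritance_probs[ekey[unname(ret_edges)]]))
    tr <- suppress_all(contained_tree(net, switching(ret_edges)))
    code <- tree_canonical_code(tr)
    if (is.null(trees[[code]])) { trees[[code]] <- tr; prob[code] <- 0 }
    prob[code] <- prob[code] + pr
  }
  list(trees = trees, prob = prob)
}

#' Network likelihood through displayed trees
#'
#' `Pr(A_1..A_m | N) = prod_i sum_T Pr(A_i | T) Pr(T | N)` where the sum
#' runs over the displayed trees and `Pr(T | N)` comes from
#' [tree_distribution()]. Two networks with identical tree distributions
#' (same trees, same lengths, same probabilities) receive identical
#' likelihoods for every possible input.
#'
#' @inheritParams tree_distribution
#' @param alignments a single [alignment()] or list of them.
#' @return likelihood in (0, 1].
#' @export
network_likelihood <- function(net, inheritance_probs, alignments) {
  if (inherits(alignments, "alignment")) alignments <- list(alignments)
  td <- tree_distribution(net, inheritance_probs)
  prod(vapply(alignments, function(a)
    sum(vapply(names(td$trees), function(code)
      tree_likelihood(td$trees[[code]], a) * td$prob[code], 0)), 0))
}
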