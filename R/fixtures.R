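# Worked-example networks.
#
# A small catalogue of networks and trees used throughout the documentation
# and tests. Each entry is built in code from an edge list; the same objects
# are shipped as extended-Newick files under inst/extdata/fixtures. The
# catalogue covers the situations that matter for identifiability theory:
# indistinguishable non-isomorphic pairs with funnels in different orders
# (fig3_*, sharing the canonical form fig4_Nprime), a network outside the
# classical tree-child/tree-sibling/galled classes that is nevertheless
# determined by its displayed trees up to three funnel out-edge lengths
# (fig5_N), clock-like funnel-free networks violating NELP with non-unique
# canonical forms (fig10_*), a reduction exercise with a transient multiedge
# (fig13_*), and wishbone/crack illustrations (fig14_*).
#
# Symbolic lengths are instantiated as lambda_i = i by default (distinct
# integers keep the fig3 family NELP); callers can override them.

net_from_edges <- function(...) {
  # arguments: alternating "u->v", lengths
  args <- list(...)
  from <- character(0); to <- character(0); lens <- list()
  i <- 1L
  while (i < length(args) || i == length(args)) {
    if (i > length(args)) break
    uv <- strsplit(args[[i]], "->", fixed = TRUE)[[1]]
    from <- c(from, trimws(uv[1])); to <- c(to, trimws(uv[2]))
    lens <- c(lens, list(args[[i + 1L]]))
    i <- i + 2L
  }
  phylo_network(cbind(from, to), lens)
}

.r <- function(x) as_rational(x)
.rsum <- function(...) Reduce(rat_add, lapply(list(...), as_rational))
.rsub <- function(a, b) rat_sub(as_rational(a), as_rational(b))

fig3_N1 <- function(lambda = 1:12) {
  l <- lapply(lambda, as_rational)
  net_from_edges(
    "r->n", l[[1]], "r->u", l[[2]], "u->s", l[[3]], "n->a", l[[4]],
    "s->m", l[[5]], "n->vb", l[[6]], "vb->b", l[[7]], "m->vb", l[[8]],
    "t->m", l[[9]], "u->t", l[[10]], "s->c", l[[11]], "t->d", l[[12]])
}

fig3_N2 <- function(lambda = 1:12, x = "1/2", y = "1/2") {
  l <- lapply(lambda, as_rational)
  x <- as_rational(x); y <- as_rational(y)
  # admissibility: -y < x < min(l6, l5 + l8), 0 < y < l7
  stopifnot(rat_cmp(rat_add(x, y), rational(0, 1)) > 0,
            rat_cmp(x, l[[6]]) < 0,
            rat_cmp(x, rat_add(l[[5]], l[[8]])) < 0,
            y$num > 0, rat_cmp(y, l[[7]]) < 0)
  net_from_edges(
    "r->n", l[[1]], "r->u", l[[2]], "u->s", l[[3]], "n->a", l[[4]],
    "s->c", l[[11]], "u->t", l[[10]], "t->d", l[[12]],
    "n->v1", rat_sub(l[[6]], x),
    "s->v1", rat_sub(rat_add(l[[5]], l[[8]]), x),
    "v1->v2", rat_add(x, y),
    "t->v2", .rsum(l[[8]], l[[9]], y),
    "v2->b", rat_sub(l[[7]], y))
}

fig4_Nprime <- function(lambda = 1:12) {
  l <- lapply(lambda, as_rational)
  net_from_edges(
    "r->n", l[[1]], "r->u", l[[2]], "n->a", l[[4]], "u->s", l[[3]],
    "u->t", l[[10]], "s->c", l[[11]], "t->d", l[[12]],
    "n->b", rat_add(l[[6]], l[[7]]),
    "s->b", .rsum(l[[5]], l[[7]], l[[8]]),
    "t->b", .rsum(l[[7]], l[[8]], l[[9]]))
}

fig5_N <- function(x = "0.05", y = "0.05", z = "0.05") {
  net_from_edges(
    "r->v1", "0.21", "r->v2", "0.34", "v1->a", "0.55", "v1->t1", "0.13",
    "t1->f1", "0.27", "t1->f3", "0.18", "v2->c", "0.62", "v2->f2", "0.23",
    "v2->f3", "0.31", "f3->s", z, "s->f1", "0.17", "s->f2", "0.29",
    "f1->b", x, "f2->d", y)
}

fig5_Npp <- function() {
  net_from_edges("r->u1", "0.3", "r->u2", "0.4", "u1->a", "0.5",
                 "u1->b", "0.2", "u2->b", "0.25", "u2->c", "0.45")
}

fig2_N1 <- function(lens = c(1, 0.5, 0.3, 0.25, 0.55, 0.2, 0.6, 0.3, 0.15)) {
  l <- lapply(lens, as_rational)
  net_from_edges("R->o", l[[1]], "R->s0", l[[2]], "s0->p1", l[[3]],
                 "s0->p2", l[[4]], "p1->a", l[[5]], "p1->w", l[[6]],
                 "p2->c", l[[7]], "p2->w", l[[8]], "w->b", l[[9]])
}

fig2_N2 <- function() {
  net_from_edges("R->o", "1", "R->u2", "0.5", "u2->m", "0.3",
                 "u2->v", "0.45", "m->u1", "0.25", "m->c", "0.55",
                 "u1->b", "0.35", "u1->v", "0.15", "v->a", "0.4")
}

fig2_N3 <- function() {
  net_from_edges("R->o", "1", "R->u2", "0.45", "u2->m", "0.35",
                 "u2->v", "0.5", "m->a", "0.6", "m->u1", "0.2",
                 "u1->b", "0.4", "u1->v", "0.1", "v->c", "0.3")
}

fig2_T1 <- function() parse_tree("(((a:0.55,b:0.35):0.25,c:0.55):0.8,o:1);")
fig2_T2 <- function() parse_tree("(((b:0.6,c:0.55):0.3,a:0.85):0.5,o:1);")

fig7_N2prime <- function() {
  net_from_edges("x0->u2", "0.5", "u2->m", "0.3", "u2->v", "0.45",
                 "m->u1", "0.25", "m->c", "0.55", "u1->b", "0.35",
                 "u1->v", "0.15", "v->a", "0.4")
}

fig7_T1prime <- function() parse_tree("((a:0.55,b:0.35):0.25,c:0.55):0.8;")
fig7_T2prime <- function() parse_tree("((b:0.6,c:0.55):0.3,a:0.85):0.5;")

fig10_a <- function() {
  net_from_edges("r->u", 1, "u->a", 1, "u->b", 1, "r->a", 2, "r->b", 2)
}

fig10_b <- function() {
  net_from_edges("r->u", 1, "r->w", 1, "u->a", 1, "u->b", 1,
                 "w->a", 1, "w->b", 1)
}

fig10_c <- function() {
  net_from_edges("r->u", 1, "r->w", 1, "r->m", 1, "u->a", 1, "u->b", 1,
                 "w->a", 1, "w->b", 1, "m->a", 1, "m->b", 1)
}

fig13_start <- function() {
  net_from_edges("r->u1", 1, "r->u2", 1, "u1->w", 1, "u1->v", 1,
                 "u2->v", 1, "v->w", 1, "w->a", 1, "w->b", 1, "u2->c", 1)
}

fig13_end <- function() {
  net_from_edges("r->u2", 1, "r->w", c(2, 3), "u2->w", 2, "u2->c", 1,
                 "w->a", 1, "w->b", 1)
}

fig14_N <- function() {
  net_from_edges("r->u", 1, "r->w", 1, "u->a", c("1", "3/2"), "u->v", 1,
                 "w->v", 1, "w->b", 1, "v->c", 1)
}

fig14_P <- function() net_from_edges("r->u", 1, "u->a", 1)
fig14_Q <- function() net_from_edges("r->u", 1, "u->a", 1, "r->w", 1, "w->b", 1)
fig14_R <- function() net_from_edges("r->u", 1, "u->v", 1, "v->c", 1,
                                     "r->w", 1, "w->v", 1)
fig14_S <- function() net_from_edges("r->u", 1, "u->a", c("1", "3/2"))

fig1_N1 <- function() fig3_N1(lambda = rep(1, 12))
fig1_N2 <- function() fig3_N2(lambda = rep(1, 12), x = "1/4", y = "1/2")

.fixture_registry <- list(
  fig1_N1 = fig1_N1, fig1_N2 = fig1_N2,
  fig2_N1 = fig2_N1, fig2_N2 = fig2_N2, fig2_N3 = fig2_N3,
  fig2_T1 = fig2_T1, fig2_T2 = fig2_T2,
  fig3_N1 = fig3_N1, fig3_N2 = fig3_N2,
  fig4_Nprime = fig4_Nprime,
  fig5_N = fig5_N, fig5_Npp = fig5_Npp,
  fig7_N2prime = fig7_N2prime, fig7_T1prime = fig7_T1prime,
  fig7_T2prime = fig7_T2prime,
  fig10_a = fig10_a, fig10_b = fig10_b, fig10_c = fig10_c,
  fig13_start = fig13_start, fig13_end = fig13_end,
  fig14_N = fig14_N, fig14_P = fig14_P, fig14_Q = fig14_Q,
  fig14_R = fig14_R, fig14_S = fig14_S)

#' Catalogue of worked-example networks and trees
#'
#' `paper_fixture(name)` returns one of the catalogued objects (see
#' `fixture_names()` for the list). The fig3 family accepts the symbolic
#' lengths `lambda` (default `1:12`) and, for `fig3_N2`, the two free
#' parameters `x` and `y` of its edge-length family, which must satisfy
#' `-y < x < min(lambda[6], lambda[5] + lambda[8])` and
#' `0 < y < lambda[7]`; every admissible choice yields a network
#' indistinguishable from `fig3_N1` with the same `lambda`. `fig5_N`
#' accepts its three unidentifiable funnel out-edge lengths `x`, `y`, `z`
#' (defaults 0.05, each anywhere in (0, 0.1)).
#'
#' @param name fixture name.
#' @param ... parameters forwarded to the fixture constructor.
#' @return a `phylo_network` or `phylo_tree`.
#' @export
paper_fixture <- function(name, ...) {
  f <- .fixture_registry[[name]]
  if (is.null(f))
    stop("unknown fixture '", name, "'; see fixture_names()", call. = FALSE)
  f(...)
}

#' @rdname paper_fixture
#' @export
fixture_names <- function() names(.fixture_registry)
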