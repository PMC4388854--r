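# Length sets: the finite sets of positive branch lengths carried by network
# edges. An edge with k lengths summarises k alternative evolutionary paths
# with the same endpoints (the compact equivalent of a k-fold multiedge).

#' Construct a length set
#'
#' A `lengthset` is a non-empty set of strictly positive exact rationals,
#' stored sorted ascending with duplicates removed.
#'
#' @param x a `rational`, numeric vector, or character vector of exact
#'   decimals/fractions.
#' @return an object of class `lengthset`.
#' @export
lengthset <- function(x) {
  r <- as_rational(x)
  if (length(r) == 0L) stop("a length set must be non-empty", call. = FALSE)
  if (any(r$num <= 0)) stop("all lengths must be strictly positive", call. = FALSE)
  r <- rat_sort(rat_unique(r))
  class(r) <- c("lengthset", "rational")
  r
}

ls_restore <- function(r) {
  r <- rat_sort(rat_unique(r))
  class(r) <- c("lengthset", "rational")
  r
}

#' Minkowski sum of two length sets
#'
#' `A + B = {a + b : a in A, b in B}` — the rule by which funnel suppression
#' combines the in-edge and out-edge lengths of a funnel. Duplicate sums
#' collapse because the result is a set.
#'
#' @param a,b `lengthset` objects.
#' @return a `lengthset`.
#' @export
ls_sum <- function(a, b) {
  grid <- expand.grid(i = seq_len(length(a)), j = seq_len(length(b)))
  num <- a$num[grid$i] * b$den[grid$j] + b$num[grid$j] * a$den[grid$i]
  den <- a$den[grid$i] * b$den[grid$j]
  ls_restore(rational(.rat_guard(num), .rat_guard(den)))
}

#' Union of length sets
#'
#' The rule by which parallel edges are merged into a single edge.
#'
#' @param a,b `lengthset` objects.
#' @return a `lengthset`.
#' @export
ls_union <- function(a, b) ls_restore(c.rational(a, b))

ls_key <- function(a) paste0("{", paste(rat_format(a), collapse = ","), "}")

ls_equal <- function(a, b) ls_key(a) == ls_key(b)

ls_shift <- function(a, delta, sign = 1) {
  # add (sign * delta) to every value; delta a scalar rational
  num <- a$num * delta$den + sign * delta$num * a$den
  r <- rational(.rat_guard(num), .rat_guard(a$den * delta$den))
  if (any(r$num <= 0))
    stop("length shift would produce a non-positive length", call. = FALSE)
  ls_restore(r)
}

#' @export
print.lengthset <- function(x, ...) {
  cat("<lengthset> ", ls_key(x), "\n", sep = "")
  invisible(x)
}
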