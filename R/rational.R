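# Exact rational arithmetic for branch lengths.
#
# Branch lengths enter the package as decimal or fractional text and must be
# compared exactly: funnel suppression forms Minkowski sums of length sets and
# the NELP check compares path-length sums for exact equality, so floating
# point is not an option. Numerators and denominators are stored as doubles
# holding exact integers; every operation reduces by the gcd and aborts if a
# magnitude could leave the exactly-representable range (2^53).

.RAT_MAX <- 2^53

rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  # vectorized Euclid; components may converge at different speeds
  repeat {
    nz <- which(b > 0)
    if (!length(nz)) break
    t <- b[nz]
    b[nz] <- a[nz] %% b[nz]
    a[nz] <- t
  }
  a
}

.rat_guard <- function(x) {
  if (any(abs(x) >= .RAT_MAX))
    stop("rational arithmetic overflow: value exceeds exact integer range",
         call. = FALSE)
  x
}

#' Construct an exact rational vector
#'
#' A `rational` is a pair of parallel numeric vectors holding exact integer
#' numerators and (positive) denominators, always reduced to lowest terms.
#'
#' @param num integer-valued numerators.
#' @param den integer-valued denominators (same length as `num`, or length 1).
#' @return an object of class `rational`.
#' @export
rational <- function(num, den = rep(1, length(num))) {
  if (length(den) == 1L) den <- rep(den, length(num))
  stopifnot(length(num) == length(den))
  if (any(den == 0)) stop("zero denominator", call. = FALSE)
  if (any(num != round(num)) || any(den != round(den)))
    stop("numerator and denominator must be integer-valued", call. = FALSE)
  .rat_guard(num); .rat_guard(den)
  s <- ifelse(den < 0, -1, 1)
  num <- num * s; den <- den * s
  g <- rat_gcd(num, den)
  g[g == 0] <- 1
  structure(list(num = num / g, den = den / g), class = "rational")
}

#' @export
length.rational <- function(x) length(x$num)

#' @export
`[.rational` <- function(x, i) rational(x$num[i], x$den[i])

#' @export
c.rational <- function(...) {
  xs <- list(...)
  rational(unlist(lapply(xs, `[[`, "num")), unlist(lapply(xs, `[[`, "den")))
}

#' Parse decimal or fractional text into exact rationals
#'
#' Accepts plain integers (`"3"`), terminating decimals (`"0.55"`) and
#' fractions (`"3/7"`). Decimal text is converted exactly, e.g. `"0.55"`
#' becomes 11/20, never a binary approximation.
#'
#' @param x character vector (numeric input is accepted only when it is
#'   integer-valued or carries few enough decimal digits to round-trip through
#'   its default print form; pass text for full control).
#' @return a `rational` of the same length.
#' @export
as_rational <- function(x) {
  if (inherits(x, "rational")) return(x)
  if (is.numeric(x)) x <- vapply(x, format_exact_numeric, character(1))
  x <- trimws(as.character(x))
  n <- length(x)
  num <- numeric(n); den <- numeric(n)
  for (i in seq_len(n)) {
    tok <- x[i]
    if (grepl("^[+-]?[0-9]+/[0-9]+$", tok)) {
      parts <- strsplit(tok, "/", fixed = TRUE)[[1]]
      num[i] <- as.numeric(parts[1]); den[i] <- as.numeric(parts[2])
    } else if (grepl("^[+-]?[0-9]+$", tok)) {
      num[i] <- as.numeric(tok); den[i] <- 1
    } else if (grepl("^[+-]?[0-9]*\\.[0-9]+$", tok)) {
      neg <- grepl("^-", tok)
      tok2 <- sub("^[+-]", "", tok)
      parts <- strsplit(tok2, ".", fixed = TRUE)[[1]]
      intpart <- if (parts[1] == "") "0" else parts[1]
      frac <- parts[2]
      den[i] <- 10^nchar(frac)
      num[i] <- (as.numeric(intpart) * den[i] + as.numeric(frac)) *
        (if (neg) -1 else 1)
    } else {
      stop(sprintf("cannot parse '%s' as an exact number", tok), call. = FALSE)
    }
  }
  rational(num, den)
}

format_exact_numeric <- function(v) {
  # default 15-significant-digit formatting round-trips typical inputs
  s <- format(v, scientific = FALSE, trim = TRUE, digits = 15)
  if (grepl("e|E", s)) stop("numeric value not representable as plain decimal")
  s
}

rat_add <- function(x, y) {
  # elementwise with recycling of scalars
  nx <- length(x); ny <- length(y)
  if (nx == 1L && ny > 1L) { x <- rational(rep(x$num, ny), rep(x$den, ny)) }
  if (ny == 1L && nx > 1L) { y <- rational(rep(y$num, nx), rep(y$den, nx)) }
  rational(.rat_guard(x$num * y$den + y$num * x$den), .rat_guard(x$den * y$den))
}

rat_sub <- function(x, y) rat_add(x, rational(-y$num, y$den))

rat_sum <- function(x) {
  acc <- rational(0, 1)
  for (i in seq_len(length(x))) acc <- rat_add(acc, x[i])
  acc
}

rat_cmp <- function(x, y) {
  # sign of x - y, elementwise
  sign(.rat_guard(x$num * y$den) - .rat_guard(y$num * x$den))
}

rat_eq <- function(x, y) x$num == y$num & x$den == y$den

rat_lt <- function(x, y) rat_cmp(x, y) < 0

rat_order <- function(x) {
  if (length(x) <= 1L) return(seq_len(length(x)))
  order(x$num / x$den, x$num, x$den)  # double ratio as primary key, exact tiebreak
}

rat_sort <- function(x) x[rat_order(x)]

rat_unique <- function(x) {
  keys <- rat_key(x)
  x[!duplicated(keys)]
}

rat_key <- function(x) paste0(x$num, "/", x$den)

#' Render exact rationals as text
#'
#' Terminating values (denominator of the form 2^a 5^b) are written as exact
#' decimals; everything else as `"p/q"`. This is the normal form used in
#' canonical codes and in the extended-Newick writer, so output text
#' re-parses to the identical rational.
#'
#' @param x a `rational`.
#' @return character vector.
#' @export
rat_format <- function(x) {
  out <- character(length(x))
  for (i in seq_len(length(x))) {
    num <- x$num[i]; den <- x$den[i]
    d <- den; a <- 0; b <- 0
    while (d %% 2 == 0) { d <- d / 2; a <- a + 1 }
    while (d %% 5 == 0) { d <- d / 5; b <- b + 1 }
    if (d != 1) {
      out[i] <- paste0(num, "/", den)
    } else if (den == 1) {
      out[i] <- as.character(num)
    } else {
      k <- max(a, b)
      scaled <- num * (10^k / den)
      if (abs(scaled) >= .RAT_MAX) { out[i] <- paste0(num, "/", den); next }
      neg <- scaled < 0
      s <- formatC(abs(scaled), format = "f", digits = 0, width = k + 1,
                   flag = "0")
      ip <- substr(s, 1, nchar(s) - k)
      fp <- substr(s, nchar(s) - k + 1, nchar(s))
      out[i] <- paste0(if (neg) "-" else "", ip, ".", fp)
    }
  }
  out
}

#' @export
format.rational <- function(x, ...) rat_format(x)

#' @export
print.rational <- function(x, ...) {
  cat("<rational> ", paste(rat_format(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.double.rational <- function(x, ...) x$num / x$den

rat_num <- function(x) x$num / x$den
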