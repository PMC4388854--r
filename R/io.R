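# Extended-Newick I/O.
#
# Dialect: standard rooted Newick, extended two ways.
#   * Hybrid tags: a node written as  name#H<k>  (name optional) may occur
#     several times; all occurrences denote the same reticulation node.
#   * Length sets: an edge carries either a single length  :x  or a set
#     :{x1,x2,...}  of positive exact decimals/fractions.
# A trailing length on the outermost group encodes a root with outdegree 1.
# Plain extended-Newick files remain valid input. Square-bracket comments
# are ignored. An edge with no stated length defaults to length 1.
#
# Parallel edges that arise from the input (e.g. two occurrences of the same
# hybrid tag under one parent) are merged into a single edge whose length set
# is the union of the parallel edges' sets: multiedges and multi-valued
# lengths are two representations of the same object and the length-set form
# is the normal form here.

.name_chars <- "A-Za-z0-9_.\\-"

parse_error <- function(kind, detail) {
  stop(sprintf("parse error (%s): %s", kind, detail), call. = FALSE)
}

#' Parse a network from extended-Newick text
#'
#' @param text a single character string (or lines that concatenate to one
#'   statement ending in `;`).
#' @return a valid `phylo_network`.
#' @examples
#' net <- parse_network("((a:1)#H1:2,(#H1:3,b:1)x:1)r;")
#' reticulation_nodes(net)
#' @export
parse_network <- function(text) {
  s <- paste(text, collapse = "")
  s <- gsub("\\[[^]]*\\]", "", s)   # strip bracket comments
  s <- gsub("[[:space:]]+", "", s)
  if (!nzchar(s)) parse_error("syntax", "empty input")
  if (!grepl(";", s, fixed = TRUE)) parse_error("syntax", "missing ';'")
  s <- sub(";.*$", "", s)

  env <- new.env(parent = emptyenv())
  env$pos <- 1L; env$str <- s; env$n <- nchar(s)
  env$from <- character(0); env$to <- character(0); env$lens <- list()
  env$hybrid <- list(); env$counter <- 0L
  env$named_leaves <- character(0)

  peek <- function() if (env$pos > env$n) "" else substr(env$str, env$pos, env$pos)
  advance <- function() env$pos <- env$pos + 1L
  expect <- function(ch) {
    if (peek() != ch)
      parse_error("syntax", sprintf("expected '%s' at position %d, found '%s'",
                                    ch, env$pos, peek()))
    advance()
  }
  read_while <- function(pattern) {
    start <- env$pos
    while (env$pos <= env$n && grepl(pattern, peek())) advance()
    substr(env$str, start, env$pos - 1L)
  }
  read_number <- function() {
    tok <- read_while("[0-9./+-]")
    if (!nzchar(tok)) parse_error("syntax",
                                  sprintf("expected a number at position %d", env$pos))
    r <- tryCatch(as_rational(tok), error = function(e)
      parse_error("number", sprintf("bad length token '%s'", tok)))
    if (any(r$num <= 0))
      parse_error("non-positive length", sprintf("length '%s' must be > 0", tok))
    r
  }
  read_lengths <- function() {
    if (peek() == "{") {
      advance()
      vals <- read_number()
      while (peek() == ",") { advance(); vals <- c.rational(vals, read_number()) }
      expect("}")
      lengthset(vals)
    } else lengthset(read_number())
  }
  new_internal <- function() {
    env$counter <- env$counter + 1L
    paste0(".i", env$counter)
  }
  hybrid_node <- function(tag, name) {
    if (is.null(env$hybrid[[tag]]))
      env$hybrid[[tag]] <- list(id = paste0(".", tag), name = "")
    if (nzchar(name)) {
      if (nzchar(env$hybrid[[tag]]$name) && env$hybrid[[tag]]$name != name)
        parse_error("hybrid", sprintf("tag %s given two names ('%s', '%s')",
                                      tag, env$hybrid[[tag]]$name, name))
      env$hybrid[[tag]]$name <- name
    }
    env$hybrid[[tag]]$id
  }

  # returns node id; caller attaches the edge
  parse_subtree <- function() {
    children <- NULL
    if (peek() == "(") {
      advance()
      children <- list(parse_branch())
      while (peek() == ",") { advance(); children <- c(children, list(parse_branch())) }
      expect(")")
    }
    name <- read_while(paste0("[", .name_chars, "]"))
    tag <- ""
    if (peek() == "#") {
      advance()
      tag <- read_while(paste0("[", .name_chars, "]"))
      if (!grepl("^H[0-9]+$", tag))
        parse_error("hybrid", sprintf("bad hybrid tag '#%s'", tag))
    }
    if (is.null(children) && !nzchar(name) && !nzchar(tag))
      parse_error("syntax", sprintf("expected a leaf name at position %d", env$pos))
    id <- if (nzchar(tag)) hybrid_node(tag, name)
          else if (is.null(children)) name
          else new_internal()
    if (is.null(children) && !nzchar(tag))
      env$named_leaves <- c(env$named_leaves, name)
    for (ch in children) {
      env$from <- c(env$from, id); env$to <- c(env$to, ch$id)
      env$lens <- c(env$lens, list(ch$len))
    }
    id
  }
  parse_branch <- function() {
    id <- parse_subtree()
    had_len <- peek() == ":"
    len <- if (had_len) { advance(); read_lengths() } else lengthset(1)
    list(id = id, len = len, had_len = had_len)
  }

  top <- parse_branch()
  if (env$pos <= env$n)
    parse_error("syntax", sprintf("unexpected trailing text '%s'",
                                  substr(env$str, env$pos, env$n)))

  from <- env$from; to <- env$to; lens <- env$lens
  # a stated top-level length means an explicit root edge
  if (top$had_len) {
    from <- c(from, ".root"); to <- c(to, top$id)
    lens <- c(lens, list(top$len))
  }

  # rename hybrid placeholder ids that received a name and are leaves
  # (names on internal nodes are decorative and ignored)
  for (tag in names(env$hybrid)) {
    h <- env$hybrid[[tag]]
    if (nzchar(h$name) && !(h$id %in% from)) {
      from[from == h$id] <- h$name; to[to == h$id] <- h$name
      env$named_leaves <- c(env$named_leaves, h$name)
    }
  }

  if (anyDuplicated(env$named_leaves))
    parse_error("duplicate leaf label",
                paste(unique(env$named_leaves[duplicated(env$named_leaves)]),
                      collapse = ","))

  # Fig-9 normalisation: merge parallel edges by length-set union
  key <- paste(from, to, sep = "\r")
  if (anyDuplicated(key)) {
    keep <- !duplicated(key)
    merged <- lens[keep]
    names(merged) <- key[keep]
    for (i in which(duplicated(key)))
      merged[[key[i]]] <- ls_union(merged[[key[i]]], lens[[i]])
    from <- from[keep]; to <- to[keep]; lens <- unname(merged)
  }

  nodes <- unique(c(from, to, top$id))
  net <- phylo_network(cbind(from, to), lens, nodes = nodes, validate = FALSE)
  bad <- validate_network(net)
  if (length(bad)) parse_error("invalid network", paste(bad, collapse = "; "))
  # unnamed hybrid leaves would be leaves with placeholder ids
  lv <- net_leaves(net)
  if (any(grepl("^\\.", lv)))
    parse_error("unnamed leaf",
                paste(lv[grepl("^\\.", lv)], collapse = ","))
  net
}

#' Write a network as extended-Newick text
#'
#' Deterministic: children are ordered by canonical code, hybrid tags are
#' numbered in order of first emission, and lengths are printed in exact
#' normal form, so `parse_network(write_network(net))` is isomorphic to
#' `net` and equal text means equal canonical code.
#'
#' @param net a valid `phylo_network`.
#' @return a single character string ending in `;`.
#' @export
write_network <- function(net) {
  codes <- node_codes(net)
  ind <- net_indegree(net)
  env <- new.env(parent = emptyenv())
  env$tags <- character(0)

  fmt_len <- function(l) {
    if (length(l) == 1L) paste0(":", rat_format(l))
    else paste0(":{", paste(rat_format(l), collapse = ","), "}")
  }
  emit <- function(v) {
    is_ret <- ind[v] > 1L
    if (is_ret && v %in% names(env$tags))
      return(paste0(if (v %in% net_leaves(net)) v else "",
                    "#", env$tags[v]))
    if (is_ret) {
      env$tags[v] <- paste0("H", length(env$tags) + 1L)
    }
    out <- edge_ids_out(net, v)
    core <- if (!length(out)) {
      v
    } else {
      ord <- order(paste0(vapply(net$lengths[out], ls_key, character(1)),
                          ">", codes[net$to[out]]))
      parts <- vapply(out[ord], function(i)
        paste0(emit(net$to[i]), fmt_len(net$lengths[[i]])), character(1))
      paste0("(", paste(parts, collapse = ","), ")",
             if (v %in% net_leaves(net)) v else "")
    }
    if (is_ret) paste0(core, "#", env$tags[v]) else core
  }

  root <- net_root(net)
  kids <- edge_ids_out(net, root)
  if (length(kids) == 1L && !(root %in% net_leaves(net))) {
    i <- kids[1]
    paste0(emit(net$to[i]), fmt_len(net$lengths[[i]]), ";")
  } else {
    paste0(emit(root), ";")
  }
}

#' Parse and write weighted trees (standard Newick)
#'
#' A tree is a network with no reticulations and one length per edge;
#' `parse_tree` enforces both (a length set `:{...}` on any edge is
#' rejected), and permits a trailing root-edge length, which encodes a root
#' of outdegree 1.
#'
#' @param text Newick text.
#' @return `parse_tree`: a `phylo_tree`; `write_tree`: character.
#' @export
parse_tree <- function(text) {
  net <- parse_network(text)
  if (length(reticulation_nodes(net)))
    parse_error("not a tree", "input contains reticulations")
  if (any(vapply(net$lengths, length, 1L) > 1L))
    parse_error("not a tree", "an edge carries more than one length")
  as_weighted_tree(net)
}

#' @rdname parse_tree
#' @param tree a `phylo_tree`.
#' @export
write_tree <- function(tree) write_network(tree)

#' Read / write extended-Newick files
#'
#' Files may contain square-bracket comment lines; the first statement
#' terminated by `;` is parsed.
#'
#' @param path file path.
#' @return `read_enewick`: a `phylo_network`.
#' @export
read_enewick <- function(path) parse_network(readLines(path, warn = FALSE))

#' @rdname read_enewick
#' @param net network to write.
#' @param comment optional comment line stored in square brackets.
#' @export
write_enewick <- function(net, path, comment = NULL) {
  lines <- character(0)
  if (!is.null(comment)) lines <- paste0("[", comment, "]")
  writeLines(c(lines, write_network(net)), path)
  invisible(path)
}
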