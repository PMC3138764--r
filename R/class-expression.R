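#' @title Description-logic class expressions
#'
#' @description Constructors for the class-expression algebra used
#'   throughout the package: named classes, \code{Thing} (top),
#'   \code{Nothing} (bottom), negation, intersection, union, and
#'   existential/universal role restrictions.  The fragment corresponds to
#'   ALC extended with role hierarchies, inverse, transitive and functional
#'   roles (declared on the ontology's role box, not in expressions).
#'
#' @details Expressions are plain lists of class \code{"dl_ce"} with a
#'   variant tag \code{op} and a canonical serialization \code{k} computed
#'   at construction time.  \code{And}/\code{Or} arguments are flattened,
#'   de-duplicated and sorted by their canonical key, so structural
#'   equality is order-insensitive and reduces to comparing keys.  A few
#'   sound simplifications are applied at construction: double negation is
#'   collapsed, \code{not Thing} becomes \code{Nothing} (and vice versa),
#'   \code{Nothing} absorbs an intersection and \code{Thing} a union.
#'
#' @param id class identifier (a non-empty string, e.g. \code{"GO:0046903"}).
#' @name class_expression
NULL

ce_build <- function(op, key, fields) {
  x <- c(list(op = op), fields, list(k = key))
  class(x) <- "dl_ce"
  x
}

#' @rdname class_expression
#' @return a \code{dl_ce} object.
#' @export
ce_named <- function(id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  ce_build("named", id, list(id = id))
}

#' @rdname class_expression
#' @export
ce_top <- function() ce_build("top", "Thing", list())

#' @rdname class_expression
#' @export
ce_bottom <- function() ce_build("bottom", "Nothing", list())

#' @rdname class_expression
#' @param e,filler a class expression.
#' @export
ce_not <- function(e) {
  stopifnot(inherits(e, "dl_ce"))
  switch(e$op,
    top = ce_bottom(),
    bottom = ce_top(),
    not = e$arg,
    ce_build("not", paste0("(not ", e$k, ")"), list(arg = e))
  )
}

ce_nary <- function(args, op) {
  stopifnot(is.list(args))
  word <- if (op == "and") " and " else " or "
  absorb <- if (op == "and") "bottom" else "top"
  drop <- if (op == "and") "top" else "bottom"
  flat <- list()
  for (a in args) {
    stopifnot(inherits(a, "dl_ce"))
    if (a$op == op) flat <- c(flat, a$args) else flat <- c(flat, list(a))
  }
  ops <- vapply(flat, `[[`, "", "op")
  if (any(ops == absorb)) return(if (op == "and") ce_bottom() else ce_top())
  flat <- flat[ops != drop]
  keys <- vapply(flat, `[[`, "", "k")
  flat <- flat[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  o <- order(keys, method = "radix")
  flat <- flat[o]
  keys <- keys[o]
  if (length(flat) == 0L) return(if (op == "and") ce_top() else ce_bottom())
  if (length(flat) == 1L) return(flat[[1L]])
  ce_build(op, paste0("(", paste(keys, collapse = word), ")"),
           list(args = flat))
}

#' @rdname class_expression
#' @param ... class expressions (or a single list of them).
#' @export
ce_and <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) && !inherits(args[[1L]], "dl_ce"))
    args <- args[[1L]]
  ce_nary(args, "and")
}

#' @rdname class_expression
#' @export
ce_or <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1L]]) && !inherits(args[[1L]], "dl_ce"))
    args <- args[[1L]]
  ce_nary(args, "or")
}

#' @rdname class_expression
#' @param role role identifier (a non-empty string, e.g. \code{"part_of"}).
#' @export
ce_some <- function(role, filler) {
  stopifnot(is.character(role), length(role) == 1L, nzchar(role),
            inherits(filler, "dl_ce"))
  ce_build("some", paste0("(", role, " some ", filler$k, ")"),
           list(role = role, filler = filler))
}

#' @rdname class_expression
#' @export
ce_only <- function(role, filler) {
  stopifnot(is.character(role), length(role) == 1L, nzchar(role),
            inherits(filler, "dl_ce"))
  ce_build("only", paste0("(", role, " only ", filler$k, ")"),
           list(role = role, filler = filler))
}

#' Test structural equality of two class expressions
#'
#' Equality is on canonical form: \code{And}/\code{Or} argument order and
#' duplicates are ignored.
#'
#' @param a,b class expressions.
#' @return logical scalar.
#' @export
ce_equal <- function(a, b) {
  stopifnot(inherits(a, "dl_ce"), inherits(b, "dl_ce"))
  identical(a$k, b$k)
}

#' Negation normal form
#'
#' Pushes negation inward until it applies only to named classes, using
#' De Morgan's laws and the duality of existential and universal
#' restrictions.  The transformation is idempotent and preserves
#' satisfiability.
#'
#' @param e a class expression.
#' @return an equivalent class expression in NNF.
#' @export
nnf <- function(e) {
  stopifnot(inherits(e, "dl_ce"))
  switch(e$op,
    named = ,
    top = ,
    bottom = e,
    and = ce_and(lapply(e$args, nnf)),
    or = ce_or(lapply(e$args, nnf)),
    some = ce_some(e$role, nnf(e$filler)),
    only = ce_only(e$role, nnf(e$filler)),
    not = {
      a <- e$arg
      switch(a$op,
        named = e,
        and = ce_or(lapply(a$args, function(x) nnf(ce_not(x)))),
        or = ce_and(lapply(a$args, function(x) nnf(ce_not(x)))),
        some = ce_only(a$role, nnf(ce_not(a$filler))),
        only = ce_some(a$role, nnf(ce_not(a$filler))),
        stop("unexpected negation argument: ", a$op)
      )
    },
    stop("unknown expression op: ", e$op)
  )
}

#' Substitute a named class inside an expression
#'
#' Used by relation-expansion templates: the template body contains the
#' placeholder class \code{?Y} which is replaced by the filler.
#'
#' @param e a class expression.
#' @param id identifier of the named class to replace.
#' @param replacement class expression substituted for each occurrence.
#' @return the rewritten expression.
#' @export
ce_substitute <- function(e, id, replacement) {
  stopifnot(inherits(e, "dl_ce"), inherits(replacement, "dl_ce"))
  switch(e$op,
    named = if (e$id == id) replacement else e,
    top = ,
    bottom = e,
    not = ce_not(ce_substitute(e$arg, id, replacement)),
    and = ce_and(lapply(e$args, ce_substitute, id = id, replacement = replacement)),
    or = ce_or(lapply(e$args, ce_substitute, id = id, replacement = replacement)),
    some = ce_some(e$role, ce_substitute(e$filler, id, replacement)),
    only = ce_only(e$role, ce_substitute(e$filler, id, replacement))
  )
}

#' Named classes occurring in an expression
#' @param e a class expression.
#' @return character vector of class identifiers (sorted, unique).
#' @export
ce_signature <- function(e) {
  acc <- switch(e$op,
    named = e$id,
    top = ,
    bottom = character(),
    not = ce_signature(e$arg),
    and = ,
    or = unlist(lapply(e$args, ce_signature)),
    some = ,
    only = ce_signature(e$filler)
  )
  sort(unique(acc))
}

#' Role identifiers occurring in an expression
#' @param e a class expression.
#' @return character vector of role identifiers (sorted, unique).
#' @export
ce_roles <- function(e) {
  acc <- switch(e$op,
    named = ,
    top = ,
    bottom = character(),
    not = ce_roles(e$arg),
    and = ,
    or = unlist(lapply(e$args, ce_roles)),
    some = ,
    only = c(e$role, ce_roles(e$filler))
  )
  sort(unique(acc))
}

# ---------------------------------------------------------------------------
# Manchester-like concrete syntax.
#
# Grammar (keywords: some only and or not Thing Nothing):
#   expr        := or_expr
#   or_expr     := and_expr ("or" and_expr)*
#   and_expr    := unary ("and" unary)*
#   unary       := "not" unary | primary
#   primary     := "(" expr ")" | IDENT ("some"|"only") unary
#                | IDENT | "Thing" | "Nothing"
# IDENT is any token that is not a keyword or parenthesis; identifiers may
# contain ":", "_", "-", "." and "?" (for the template placeholder "?Y").
# The canonical printer emits a fully parenthesized form; the parser accepts
# both that and the usual lightly-parenthesized style.
# ---------------------------------------------------------------------------

ce_tokenize <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1L]]
  toks[nzchar(toks)]
}

#' Parse a Manchester-style class expression
#'
#' Accepts the keywords \code{some}, \code{only}, \code{and}, \code{or},
#' \code{not}, \code{Thing} and \code{Nothing}, with parentheses for
#' grouping.  \code{and} binds tighter than \code{or}; restrictions
#' (\code{R some C}, \code{R only C}) bind tighter than both.
#'
#' @param text a single character string, e.g.
#'   \code{"Quality and inheres_in some (part_of some Liver)"}.
#' @return a \code{dl_ce} class expression.
#' @export
parse_class_expression <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- ce_tokenize(text)
  if (length(toks) == 0L) stop("empty class expression")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NA_character_
  advance <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  expect <- function(what) {
    t <- advance()
    if (is.na(t) || t != what)
      stop(sprintf("expected '%s' at token %d of '%s'", what, pos - 1L, text))
    t
  }
  keywords <- c("some", "only", "and", "or", "not", "(", ")")

  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && peek() == "or") {
      advance()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1L]] else ce_or(args)
  }
  parse_and <- function() {
    args <- list(parse_unary())
    while (!is.na(peek()) && peek() == "and") {
      advance()
      args <- c(args, list(parse_unary()))
    }
    if (length(args) == 1L) args[[1L]] else ce_and(args)
  }
  parse_unary <- function() {
    if (!is.na(peek()) && peek() == "not") {
      advance()
      return(ce_not(parse_unary()))
    }
    parse_primary()
  }
  parse_primary <- function() {
    t <- advance()
    if (is.na(t)) stop("unexpected end of expression in '", text, "'")
    if (t == "(") {
      e <- parse_or()
      expect(")")
      return(e)
    }
    if (t %in% keywords) stop("unexpected token '", t, "' in '", text, "'")
    if (t == "Thing") return(ce_top())
    if (t == "Nothing") return(ce_bottom())
    nxt <- peek()
    if (!is.na(nxt) && nxt %in% c("some", "only")) {
      advance()
      filler <- parse_unary()
      return(if (nxt == "some") ce_some(t, filler) else ce_only(t, filler))
    }
    ce_named(t)
  }

  e <- parse_or()
  if (!is.na(peek()))
    stop("trailing tokens after expression: '", peek(), "' in '", text, "'")
  e
}

#' Serialize a class expression to Manchester-like text
#'
#' The output is the canonical fully parenthesized form;
#' \code{parse_class_expression(format_class_expression(e))} reconstructs
#' \code{e} exactly.
#'
#' @param e a class expression.
#' @return a character string.
#' @export
format_class_expression <- function(e) {
  stopifnot(inherits(e, "dl_ce"))
  e$k
}

#' @export
print.dl_ce <- function(x, ...) {
  cat("<class expression> ", x$k, "\n", sep = "")
  invisible(x)
}

#' @export
format.dl_ce <- function(x, ...) x$k

#' @export
as.character.dl_ce <- function(x, ...) x$k
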