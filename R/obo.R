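#' @title OBO 1.2 Flatfile input/output
#'
#' @description A faithful in-memory image of an OBO Flatfile: a header
#'   (key/value pairs), a sequence of term frames and a sequence of
#'   typedef frames.  Unknown tags are preserved verbatim so that
#'   \code{write_obo(parse_obo(x))} round-trips structurally.  Trailing
#'   qualifier blocks (\code{{...}}) are kept but ignored by conversion;
#'   trailing \code{!} comments are stripped.
#' @name obo_io
NULL

obo_strip <- function(value) {
  value <- sub("\\s+!.*$", "", value)
  qual <- NA_character_
  m <- regmatches(value, regexpr("\\{[^}]*\\}\\s*$", value))
  if (length(m) == 1L && nzchar(m)) {
    qual <- trimws(m)
    value <- sub("\\{[^}]*\\}\\s*$", "", value)
  }
  list(value = trimws(value), qualifier = qual)
}

new_term_frame <- function(id = NA_character_) {
  list(id = id, name = NA_character_, namespace = NA_character_,
       is_a = character(),
       relationship = list(),     # list of c(relation, target)
       intersection_of = list(),  # list of c(relation-or-NA, target)
       disjoint_from = character(),
       is_obsolete = FALSE,
       other = list(),            # list of c(tag, value) in input order
       line = NA_integer_)
}

new_typedef_frame <- function(id = NA_character_) {
  list(id = id, name = NA_character_,
       is_transitive = FALSE, is_symmetric = FALSE, is_reflexive = FALSE,
       is_functional = FALSE,
       domain = NA_character_, range = NA_character_,
       inverse_of = NA_character_,
       is_a = character(),
       other = list(), line = NA_integer_)
}

#' Parse an OBO 1.2 Flatfile
#'
#' Every \code{[Term]} and \code{[Typedef]} stanza is mapped to a frame;
#' stanzas of other types and unknown tags are preserved opaquely.  Line
#' numbers are recorded for provenance.  Malformed tag lines raise an
#' error naming the offending line.
#'
#' @param text either a single string containing the whole document, a
#'   character vector of lines, or a file path (see \code{read_obo}).
#' @return an object of class \code{obo_document} with fields
#'   \code{header}, \code{terms}, \code{typedefs} and \code{warnings}.
#' @export
parse_obo <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- as.character(text)
  doc <- structure(list(header = list(), terms = list(), typedefs = list(),
                        other_stanzas = list(), warnings = character()),
                   class = "obo_document")
  state <- "header"   # header | term | typedef | other
  frame <- NULL
  flush <- function() {
    if (is.null(frame)) return()
    if (state == "term") {
      if (is.na(frame$id)) stop("term stanza without id (line ", frame$line, ")")
      if (!is.null(doc$terms[[frame$id]]))
        stop("duplicate term id: ", frame$id)
      if (length(frame$intersection_of) == 1L)
        doc$warnings <<- c(doc$warnings, sprintf(
          "term %s: intersection_of with a single element (line %d)",
          frame$id, frame$line))
      doc$terms[[frame$id]] <<- frame
    } else if (state == "typedef") {
      if (is.na(frame$id)) stop("typedef stanza without id (line ", frame$line, ")")
      if (!is.null(doc$typedefs[[frame$id]]))
        stop("duplicate typedef id: ", frame$id)
      doc$typedefs[[frame$id]] <<- frame
    } else if (state == "other") {
      doc$other_stanzas[[length(doc$other_stanzas) + 1L]] <<- frame
    }
    frame <<- NULL
  }
  for (i in seq_along(lines)) {
    raw <- lines[[i]]
    line <- trimws(raw)
    if (!nzchar(line) || startsWith(line, "!")) next
    if (startsWith(line, "[")) {
      if (!grepl("^\\[[A-Za-z_]+\\]$", line))
        stop("malformed stanza header at line ", i, ": ", raw)
      flush()
      kind <- substr(line, 2L, nchar(line) - 1L)
      if (kind == "Term") {
        state <- "term"
        frame <- new_term_frame()
      } else if (kind == "Typedef") {
        state <- "typedef"
        frame <- new_typedef_frame()
      } else {
        state <- "other"
        frame <- list(kind = kind, tags = list(), line = i)
      }
      frame$line <- i
      next
    }
    m <- regexec("^([A-Za-z0-9_-]+):\\s*(.*)$", line)[[1L]]
    if (m[1L] == -1L) stop("malformed tag line at line ", i, ": ", raw)
    tag <- regmatches(line, regexec("^([A-Za-z0-9_-]+):\\s*(.*)$", line))[[1L]]
    key <- tag[2L]
    sv <- obo_strip(tag[3L])
    val <- sv$value
    if (state == "header") {
      doc$header[[length(doc$header) + 1L]] <- c(key, val)
      next
    }
    if (state == "other") {
      frame$tags[[length(frame$tags) + 1L]] <- c(key, val)
      next
    }
    if (state == "term") {
      if (key == "id") frame$id <- val
      else if (key == "name") frame$name <- val
      else if (key == "namespace") frame$namespace <- val
      else if (key == "is_a") frame$is_a <- c(frame$is_a, val)
      else if (key == "relationship") {
        parts <- strsplit(val, "\\s+")[[1L]]
        if (length(parts) < 2L)
          stop("malformed relationship at line ", i, ": ", raw)
        frame$relationship[[length(frame$relationship) + 1L]] <-
          c(parts[1L], parts[2L])
      } else if (key == "intersection_of") {
        parts <- strsplit(val, "\\s+")[[1L]]
        entry <- if (length(parts) >= 2L) c(parts[1L], parts[2L])
                 else c(NA_character_, parts[1L])
        frame$intersection_of[[length(frame$intersection_of) + 1L]] <- entry
      } else if (key == "disjoint_from")
        frame$disjoint_from <- c(frame$disjoint_from, val)
      else if (key == "is_obsolete") frame$is_obsolete <- identical(val, "true")
      else frame$other[[length(frame$other) + 1L]] <- c(key, val)
    } else { # typedef
      if (key == "id") frame$id <- val
      else if (key == "name") frame$name <- val
      else if (key == "is_transitive") frame$is_transitive <- identical(val, "true")
      else if (key == "is_symmetric") frame$is_symmetric <- identical(val, "true")
      else if (key == "is_reflexive") frame$is_reflexive <- identical(val, "true")
      else if (key == "is_functional") frame$is_functional <- identical(val, "true")
      else if (key == "domain") frame$domain <- val
      else if (key == "range") frame$range <- val
      else if (key == "inverse_of") frame$inverse_of <- val
      else if (key == "is_a") frame$is_a <- c(frame$is_a, val)
      else frame$other[[length(frame$other) + 1L]] <- c(key, val)
    }
  }
  flush()
  doc
}

#' Read an OBO file from disk
#' @param path file path.
#' @return an \code{obo_document}.
#' @export
read_obo <- function(path) {
  parse_obo(readLines(path, warn = FALSE, encoding = "UTF-8"))
}

#' @export
print.obo_document <- function(x, ...) {
  cat(sprintf("<obo document> %d terms, %d typedefs, %d header lines\n",
              length(x$terms), length(x$typedefs), length(x$header)))
  invisible(x)
}

format_term_frame <- function(f) {
  out <- c("[Term]", paste0("id: ", f$id))
  if (!is.na(f$name)) out <- c(out, paste0("name: ", f$name))
  if (!is.na(f$namespace)) out <- c(out, paste0("namespace: ", f$namespace))
  for (v in f$is_a) out <- c(out, paste0("is_a: ", v))
  for (e in f$intersection_of) {
    out <- c(out, if (is.na(e[1L]))
      paste0("intersection_of: ", e[2L])
    else
      paste0("intersection_of: ", e[1L], " ", e[2L]))
  }
  for (e in f$relationship)
    out <- c(out, paste0("relationship: ", e[1L], " ", e[2L]))
  for (v in f$disjoint_from) out <- c(out, paste0("disjoint_from: ", v))
  if (isTRUE(f$is_obsolete)) out <- c(out, "is_obsolete: true")
  for (e in f$other) out <- c(out, paste0(e[1L], ": ", e[2L]))
  out
}

format_typedef_frame <- function(f) {
  out <- c("[Typedef]", paste0("id: ", f$id))
  if (!is.na(f$name)) out <- c(out, paste0("name: ", f$name))
  for (v in f$is_a) out <- c(out, paste0("is_a: ", v))
  if (!is.na(f$domain)) out <- c(out, paste0("domain: ", f$domain))
  if (!is.na(f$range)) out <- c(out, paste0("range: ", f$range))
  if (!is.na(f$inverse_of)) out <- c(out, paste0("inverse_of: ", f$inverse_of))
  if (isTRUE(f$is_transitive)) out <- c(out, "is_transitive: true")
  if (isTRUE(f$is_symmetric)) out <- c(out, "is_symmetric: true")
  if (isTRUE(f$is_reflexive)) out <- c(out, "is_reflexive: true")
  if (isTRUE(f$is_functional)) out <- c(out, "is_functional: true")
  for (e in f$other) out <- c(out, paste0(e[1L], ": ", e[2L]))
  out
}

#' Serialize an OBO document
#'
#' Tag order within each stanza is deterministic: id, name, namespace,
#' is_a, intersection_of, relationship, disjoint_from, is_obsolete, then
#' preserved unknown tags in input order.
#'
#' @param doc an \code{obo_document}.
#' @param path optional file path; when given the text is written there.
#' @return invisibly, the character vector of lines.
#' @export
write_obo <- function(doc, path = NULL) {
  stopifnot(inherits(doc, "obo_document"))
  out <- character()
  if (length(doc$header) == 0L) out <- "format-version: 1.2"
  for (h in doc$header) out <- c(out, paste0(h[1L], ": ", h[2L]))
  for (f in doc$terms) out <- c(out, "", format_term_frame(f))
  for (f in doc$typedefs) out <- c(out, "", format_typedef_frame(f))
  for (s in doc$other_stanzas) {
    out <- c(out, "", paste0("[", s$kind, "]"))
    for (e in s$tags) out <- c(out, paste0(e[1L], ": ", e[2L]))
  }
  if (!is.null(path)) writeLines(out, path, useBytes = TRUE)
  invisible(out)
}

#' Count relation usage across OBO documents
#'
#' Tallies, for every relation identifier occurring anywhere, the number
#' of \code{relationship:} lines and the number of relational
#' \code{intersection_of:} lines (cross-product differentia) that use it.
#'
#' @param docs an \code{obo_document} or a list of them.
#' @return a data frame with columns \code{relation},
#'   \code{n_relationship}, \code{n_definition}, sorted by
#'   \code{n_relationship} descending (ties broken by relation id).
#' @export
count_relation_usage <- function(docs) {
  if (inherits(docs, "obo_document")) docs <- list(docs)
  rel <- character(); def <- character()
  for (doc in docs) {
    for (f in doc$terms) {
      for (e in f$relationship) rel <- c(rel, e[1L])
      for (e in f$intersection_of) if (!is.na(e[1L])) def <- c(def, e[1L])
    }
  }
  ids <- sort(unique(c(rel, def)))
  out <- data.frame(
    relation = ids,
    n_relationship = vapply(ids, function(i) sum(rel == i), 0L),
    n_definition = vapply(ids, function(i) sum(def == i), 0L),
    stringsAsFactors = FALSE)
  out <- out[order(-out$n_relationship, out$relation), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count defined (cross-product) terms
#'
#' A defined term is a non-obsolete term frame with a non-empty
#' \code{intersection_of} definition.
#'
#' @param doc an \code{obo_document}.
#' @return a non-negative integer.
#' @export
count_defined_terms <- function(doc) {
  stopifnot(inherits(doc, "obo_document"))
  sum(vapply(doc$terms, function(f) {
    !isTRUE(f$is_obsolete) && length(f$intersection_of) > 0L
  }, TRUE))
}

#' Identifiers referenced but not declared in a set of documents
#'
#' @param docs an \code{obo_document} or a list of them.
#' @return a data frame with columns \code{id}, \code{referenced_by},
#'   \code{via}; empty when every reference resolves.
#' @export
dangling_references <- function(docs) {
  if (inherits(docs, "obo_document")) docs <- list(docs)
  declared <- unlist(lapply(docs, function(d)
    c(names(d$terms), names(d$typedefs))))
  rows <- list()
  note <- function(id, by, via) {
    rows[[length(rows) + 1L]] <<- data.frame(id = id, referenced_by = by,
                                             via = via, stringsAsFactors = FALSE)
  }
  for (doc in docs) {
    for (f in doc$terms) {
      for (v in f$is_a) if (!(v %in% declared)) note(v, f$id, "is_a")
      for (e in f$relationship)
        if (!(e[2L] %in% declared)) note(e[2L], f$id, "relationship")
      for (e in f$intersection_of)
        if (!(e[2L] %in% declared)) note(e[2L], f$id, "intersection_of")
      for (v in f$disjoint_from)
        if (!(v %in% declared)) note(v, f$id, "disjoint_from")
    }
  }
  if (length(rows) == 0L)
    return(data.frame(id = character(), referenced_by = character(),
                      via = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Build an OBO document programmatically
#'
#' Convenience constructor used by the fixtures module and tests.
#'
#' @param terms list of term frames (see \code{obo_term}).
#' @param typedefs list of typedef frames (see \code{obo_typedef}).
#' @param header list of \code{c(key, value)} pairs.
#' @return an \code{obo_document}.
#' @export
obo_document <- function(terms = list(), typedefs = list(),
                         header = list(c("format-version", "1.2"))) {
  doc <- structure(list(header = header, terms = list(), typedefs = list(),
                        other_stanzas = list(), warnings = character()),
                   class = "obo_document")
  for (f in terms) doc$terms[[f$id]] <- f
  for (f in typedefs) doc$typedefs[[f$id]] <- f
  doc
}

#' @rdname obo_document
#' @param id identifier.
#' @param name human-readable label.
#' @param namespace optional namespace (e.g. \code{"biological_process"}).
#' @param is_a character vector of parent identifiers.
#' @param relationship list of \code{c(relation, target)} pairs.
#' @param intersection_of list of \code{c(relation-or-NA, target)} pairs;
#'   a plain genus entry is written as \code{c(NA, target)} or just the
#'   target string.
#' @param disjoint_from character vector of identifiers.
#' @param is_obsolete logical flag.
#' @export
obo_term <- function(id, name = NA_character_, namespace = NA_character_,
                     is_a = character(), relationship = list(),
                     intersection_of = list(), disjoint_from = character(),
                     is_obsolete = FALSE) {
  f <- new_term_frame(id)
  f$name <- name
  f$namespace <- namespace
  f$is_a <- as.character(is_a)
  f$relationship <- lapply(relationship, function(e) as.character(e))
  f$intersection_of <- lapply(intersection_of, function(e) {
    e <- as.character(e)
    if (length(e) == 1L) c(NA_character_, e) else e
  })
  f$disjoint_from <- as.character(disjoint_from)
  f$is_obsolete <- isTRUE(is_obsolete)
  f
}

#' @rdname obo_document
#' @param is_transitive,is_symmetric,is_reflexive,is_functional logical
#'   characteristic flags.
#' @param domain,range optional term identifiers.
#' @param inverse_of optional relation identifier.
#' @export
obo_typedef <- function(id, name = NA_character_, is_transitive = FALSE,
                        is_symmetric = FALSE, is_reflexive = FALSE,
                        is_functional = FALSE, domain = NA_character_,
                        range = NA_character_, inverse_of = NA_character_,
                        is_a = character()) {
  f <- new_typedef_frame(id)
  f$name <- name
  f$is_transitive <- isTRUE(is_transitive)
  f$is_symmetric <- isTRUE(is_symmetric)
  f$is_reflexive <- isTRUE(is_reflexive)
  f$is_functional <- isTRUE(is_functional)
  f$domain <- domain
  f$range <- range
  f$inverse_of <- inverse_of
  f$is_a <- as.character(is_a)
  f
}
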