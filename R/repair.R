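#' @title Disambiguating ambiguously used relations
#'
#' @description A relation used with two formally disjoint meanings (for
#'   instance \code{has_central_participant}, intended between a process
#'   and a material object but often asserted between a quality and a
#'   material object) is expanded \emph{disjunctively} over all its
#'   candidate meanings.  Because only one disjunct can be satisfiable
#'   for a given class, the reasoner resolves each use; resolved
#'   "unintended" uses are rewritten in the source document with a new
#'   composite relation (e.g. \code{inheres_in_has_central_participant}),
#'   after which strict conversion no longer produces the contradiction.
#' @name repair
NULL

#' Construct a disambiguation rule
#'
#' @param relation the ambiguous relation identifier.
#' @param alternatives list of at least one \code{relation_template} (or
#'   Manchester body strings with \code{?Y}); the first alternative is the
#'   relation's intended meaning.
#' @param replacement_names character vector, parallel to
#'   \code{alternatives}: the relation identifier a use resolved to that
#'   meaning is rewritten to (the intended meaning keeps the original
#'   name).
#' @return a \code{disambiguation_rule}.
#' @export
disambiguation_rule <- function(relation, alternatives, replacement_names) {
  alternatives <- lapply(alternatives, function(a) {
    if (inherits(a, "relation_template")) a else relation_template(relation, a)
  })
  stopifnot(length(alternatives) >= 1L,
            length(replacement_names) == length(alternatives))
  structure(list(relation = relation, alternatives = alternatives,
                 replacement_names = as.character(replacement_names)),
            class = "disambiguation_rule")
}

#' Built-in disambiguation rules
#'
#' Four rules: \code{has_output} and \code{has_input} (a process has the
#' filler as output/input, or a \emph{function} realized by such
#' processes); \code{inheres_in} (a quality of the filler, or a quality
#' of processes the filler participates in); and
#' \code{has_central_participant} (a process relation, or a quality of
#' such a process).  The first alternative is always the intended
#' meaning.  The function-reading alternatives carry an explicit
#' \code{Function} conjunct: a bare universal restriction over
#' \code{realized_by} is vacuously satisfiable for process classes,
#' which would leave every intended use "ambiguous"; the conjunct makes
#' the two meanings formally disjoint, which is what lets reasoning
#' eliminate one branch.  (The composite relations introduced on
#' rewriting keep the plain universal-restriction template: after
#' rewriting, the class's upper-level root carries the disambiguated
#' information.)
#'
#' @return named list of \code{disambiguation_rule} objects.
#' @export
disambiguation_rules <- function() {
  list(
    has_output = disambiguation_rule(
      "has_output",
      list("has_output some ?Y",
           "Function and (realized_by only (has_output some ?Y))"),
      c("has_output", "realized_by_has_output")),
    has_input = disambiguation_rule(
      "has_input",
      list("has_input some ?Y",
           "Function and (realized_by only (has_input some ?Y))"),
      c("has_input", "realized_by_has_input")),
    inheres_in = disambiguation_rule(
      "inheres_in",
      list("inheres_in some ?Y",
           "inheres_in some (has_participant some ?Y)"),
      c("inheres_in", "inheres_in_has_participant")),
    has_central_participant = disambiguation_rule(
      "has_central_participant",
      list("has_central_participant some ?Y",
           "inheres_in some (has_central_participant some ?Y)"),
      c("has_central_participant", "inheres_in_has_central_participant"))
  )
}

#' Expand a filler through a disambiguation rule
#'
#' Produces the disjunction of all the rule's alternative expansions; a
#' single-alternative rule degenerates to the plain expansion.
#'
#' @param rule a \code{disambiguation_rule}.
#' @param filler a class expression.
#' @return a class expression.
#' @export
disambiguated_expand <- function(rule, filler) {
  stopifnot(inherits(rule, "disambiguation_rule"), inherits(filler, "dl_ce"))
  parts <- lapply(rule$alternatives, expand_template, filler = filler)
  if (length(parts) == 1L) parts[[1L]] else ce_or(parts)
}

#' Resolve each use of an ambiguous relation to its meaning
#'
#' The ontology must have been converted with the rule's relation listed
#' in the configuration's \code{disambiguate} set.  For every recorded
#' use, each alternative is substituted (alone) for the disjunction in
#' that class's definition and the class's satisfiability is re-tested:
#' exactly one satisfiable alternative resolves the use to that meaning
#' (\code{"intended"} for the first alternative, \code{"unintended"}
#' otherwise); several satisfiable alternatives leave it
#' \code{"ambiguous"}; none leaves it \code{"neither"}.  Classes with
#' several ambiguous uses are tested one use at a time, the other uses
#' keeping their (weaker) disjunctive expansion, which localizes each
#' test.
#'
#' @param o an ontology produced by \code{\link{convert_obo}} with
#'   disambiguation enabled for \code{rule$relation}.
#' @param rule a \code{disambiguation_rule}.
#' @param ... passed to \code{\link{is_satisfiable}}.
#' @return a \code{resolution_report}: data frame with columns
#'   \code{class}, \code{relation}, \code{target}, \code{use_index},
#'   \code{context}, \code{status}, \code{meaning} (the resolved
#'   replacement relation name, \code{NA} unless resolved); attribute
#'   \code{counts} tallies statuses.
#' @export
resolve_uses <- function(o, rule, ...) {
  stopifnot(inherits(o, "dl_ontology"), inherits(rule, "disambiguation_rule"))
  cfg <- attr(o, "config")
  docs <- attr(o, "docs")
  uses <- attr(o, "uses")
  if (is.null(cfg) || is.null(docs) || is.null(uses))
    stop("ontology lacks conversion metadata; build it with convert_obo()")
  if (!(rule$relation %in% cfg$disambiguate))
    stop("ontology was not converted with disambiguation for ",
         rule$relation)
  uses <- uses[uses$relation == rule$relation, , drop = FALSE]
  n_alt <- length(rule$alternatives)
  rows <- list()
  for (i in seq_len(nrow(uses))) {
    u <- uses[i, ]
    sat <- logical(n_alt)
    undecided <- FALSE
    for (j in seq_len(n_alt)) {
      oj <- convert_impl(docs, cfg,
                         pin = list(class = u$class, relation = u$relation,
                                    index = u$use_index, alternative = j))
      v <- is_satisfiable(oj, ce_named(u$class), ...)
      if (is.na(v)) undecided <- TRUE
      sat[j] <- isTRUE(v)
    }
    status <- if (undecided) "undecided"
      else if (sum(sat) == 0L) "neither"
      else if (sum(sat) > 1L) "ambiguous"
      else if (which(sat) == 1L) "intended"
      else "unintended"
    meaning <- if (status %in% c("intended", "unintended"))
      rule$replacement_names[which(sat)] else NA_character_
    rows[[length(rows) + 1L]] <- data.frame(
      class = u$class, relation = u$relation, target = u$target,
      use_index = u$use_index, context = u$context, status = status,
      meaning = meaning, stringsAsFactors = FALSE)
  }
  rep <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(class = character(), relation = character(),
               target = character(), use_index = integer(),
               context = character(), status = character(),
               meaning = character(), stringsAsFactors = FALSE)
  rep <- rep[order(rep$class, rep$use_index), , drop = FALSE]
  rownames(rep) <- NULL
  attr(rep, "counts") <- table(factor(rep$status,
    levels = c("intended", "unintended", "ambiguous", "neither",
               "undecided")))
  class(rep) <- c("resolution_report", class(rep))
  rep
}

#' @export
print.resolution_report <- function(x, ...) {
  cat("<resolution report>\n")
  print(attr(x, "counts"))
  NextMethod()
}

#' Rewrite resolved unintended relation uses in the source document
#'
#' Every use resolved to an unintended meaning has its relation
#' identifier replaced by the rule's composite replacement name in the
#' corresponding \code{relationship:} or \code{intersection_of:} line.
#' Uses with status \code{"ambiguous"}, \code{"neither"} or
#' \code{"undecided"} are left untouched and returned in the
#' \code{skipped} attribute.
#'
#' @param doc an \code{obo_document}.
#' @param report a \code{resolution_report} (possibly the concatenation
#'   of several rules' reports).
#' @param rules named list of \code{disambiguation_rule}s (default: the
#'   built-ins).
#' @param cfg the \code{conversion_config} used for conversion (its
#'   synonym map identifies which raw relation spellings correspond to
#'   the canonical identifier being rewritten).
#' @return the rewritten \code{obo_document}; attribute \code{skipped}
#'   lists unresolved uses.
#' @export
rewrite_resolved <- function(doc, report, rules = disambiguation_rules(),
                             cfg = conversion_config()) {
  stopifnot(inherits(doc, "obo_document"))
  skipped <- report[!(report$status %in% c("intended", "unintended")), ,
                    drop = FALSE]
  todo <- report[report$status == "unintended", , drop = FALSE]
  for (i in seq_len(nrow(todo))) {
    u <- todo[i, ]
    f <- doc$terms[[u$class]]
    if (is.null(f)) next
    replacement <- u$meaning
    seen <- 0L
    if (length(f$relationship) > 0L) {
      for (j in seq_along(f$relationship)) {
        e <- f$relationship[[j]]
        if (resolve_relation_id(e[1L], cfg) == u$relation) {
          seen <- seen + 1L
          if (seen == u$use_index) f$relationship[[j]][1L] <- replacement
        }
      }
    }
    if (length(f$intersection_of) > 0L) {
      for (j in seq_along(f$intersection_of)) {
        e <- f$intersection_of[[j]]
        if (!is.na(e[1L]) && resolve_relation_id(e[1L], cfg) == u$relation) {
          seen <- seen + 1L
          if (seen == u$use_index) f$intersection_of[[j]][1L] <- replacement
        }
      }
    }
    doc$terms[[u$class]] <- f
  }
  attr(doc, "skipped") <- skipped
  doc
}

#' Compare unsatisfiable-class sets before and after a repair
#'
#' @param before,after ontologies (typically strict conversions of the
#'   original and the rewritten document).
#' @param ... passed to \code{\link{unsatisfiable_classes}}.
#' @return list with \code{removed} (classes unsatisfiable before but
#'   not after) and \code{remaining} (still unsatisfiable after).
#' @export
compare_unsat <- function(before, after, ...) {
  ub <- unsatisfiable_classes(before, ...)
  ua <- unsatisfiable_classes(after, ...)
  list(removed = sort(setdiff(ub, ua)), remaining = sort(unname(ua)))
}
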