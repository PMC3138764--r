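#' @title Converting OBO documents into description-logic axioms
#'
#' @description The formalization step: every class-class relation
#'   statement is expanded through a single-argument template into a class
#'   expression, \code{is_a} lines become subclass axioms,
#'   \code{intersection_of} cross-product definitions become equivalence
#'   axioms, \code{disjoint_from} lines become disjointness axioms, and
#'   every class is aligned to one of the four upper-level roots.
#' @name conversion
NULL

term_prefix <- function(id) {
  if (grepl(":", id, fixed = TRUE)) sub(":.*$", "", id) else NA_character_
}

resolve_relation_id <- function(rel, cfg) {
  rc <- canonical_relation_id(rel)
  if (rc %in% names(cfg$synonyms)) rc <- unname(cfg$synonyms[[rc]])
  rc
}

#' Convert OBO documents to an ontology
#'
#' For each non-obsolete term \code{C}: each \code{is_a: D} line yields
#' \code{C SubClassOf D} (omitted under \code{strip_asserted_isa}); each
#' \code{relationship: R D} line yields
#' \code{C SubClassOf expand(template(R), D)}; a non-empty
#' \code{intersection_of} yields
#' \code{C EquivalentTo And(conjuncts)} where a plain genus entry
#' contributes the named class and a relational entry its template
#' expansion; each \code{disjoint_from: D} yields a disjointness axiom.
#' Relation identifiers are canonicalized through the synonym map first.
#' Unregistered relations expand with the default template
#' \code{R some ?Y} over a fresh primitive role; relations matching a
#' composite-domain rule (by default \code{results_in*}) stay primitive
#' and receive the rule's domain class.  Relations listed in
#' \code{cfg$disambiguate} are expanded disjunctively over their
#' registered \code{\link{disambiguation_rules}}.  The upper-level
#' ontology, the root assignments and (optionally) the PATO quality
#' constraints are merged in.  Every axiom carries provenance
#' (\code{doc<i>:<line>:<tag>:<class>}).
#'
#' @param docs an \code{obo_document} or a list of them.
#' @param cfg a \code{\link{conversion_config}}.
#' @return a \code{dl_ontology}; attributes \code{dangling} (reference
#'   report), \code{uses} (per-class relation-use table, consumed by the
#'   repair module), \code{typedef_conflicts}, \code{config} and
#'   \code{docs}.
#' @export
convert_obo <- function(docs, cfg = conversion_config()) {
  convert_impl(docs, cfg, pin = NULL)
}

convert_impl <- function(docs, cfg, pin = NULL) {
  stopifnot(inherits(cfg, "conversion_config"))
  if (inherits(docs, "obo_document")) docs <- list(docs)
  o <- build_upper_ontology()
  if (!cfg$functional_inheres_in) {
    o$roles[["inheres_in"]]$functional <- FALSE
  }
  rules <- disambiguation_rules()
  conflicts <- list()

  # typedef metadata: the template registry wins; typedef flags are merged
  # where the role is otherwise unconstrained, conflicts are reported
  for (di in seq_along(docs)) {
    for (td in docs[[di]]$typedefs) {
      rc <- resolve_relation_id(td$id, cfg)
      existing <- o$roles[[rc]]
      if (is.null(existing)) {
        dom <- if (!is.na(td$domain)) ce_named(td$domain) else NULL
        rng <- if (!is.na(td$range)) ce_named(td$range) else NULL
        o <- add_role(o, role_declaration(
          rc, transitive = td$is_transitive, reflexive = td$is_reflexive,
          symmetric = td$is_symmetric, functional = td$is_functional,
          inverse = if (!is.na(td$inverse_of))
            resolve_relation_id(td$inverse_of, cfg) else NA_character_,
          super_roles = vapply(td$is_a, resolve_relation_id, "", cfg = cfg),
          domain = dom, range = rng))
      } else {
        for (fl in c("is_transitive", "is_reflexive", "is_symmetric",
                     "is_functional")) {
          target <- sub("^is_", "", fl)
          if (isTRUE(td[[fl]]) && !isTRUE(existing[[target]]))
            conflicts[[length(conflicts) + 1L]] <-
              sprintf("typedef %s asserts %s but declaration of %s does not",
                      td$id, fl, rc)
        }
      }
    }
  }

  uses <- list()
  use_counter <- new.env(parent = emptyenv())
  next_use <- function(class_id, rel) {
    key <- paste0(class_id, "\r", rel)
    n <- (get0(key, use_counter) %||% 0L) + 1L
    assign(key, n, use_counter)
    n
  }

  expand_relation <- function(rel, target_id, class_id, context) {
    rc <- resolve_relation_id(rel, cfg)
    filler <- ce_named(target_id)
    idx <- next_use(class_id, rc)
    uses[[length(uses) + 1L]] <<- data.frame(
      class = class_id, relation = rc, target = target_id,
      context = context, use_index = idx, stringsAsFactors = FALSE)
    if (rc %in% cfg$disambiguate && !is.null(rules[[rc]])) {
      rule <- rules[[rc]]
      pinned <- !is.null(pin) && pin$class == class_id &&
        pin$relation == rc && pin$index == idx
      if (pinned) {
        return(expand_template(rule$alternatives[[pin$alternative]], filler))
      }
      return(disambiguated_expand(rule, filler))
    }
    t <- cfg$templates[[rc]]
    if (!is.null(t)) return(expand_template(t, filler))
    # unregistered relation: fresh primitive role, composite-domain rules
    if (is.null(o$roles[[rc]])) {
      dom <- NULL
      for (pat in names(cfg$composite_domain_rules)) {
        if (grepl(pat, rc))
          dom <- ce_named(unname(cfg$composite_domain_rules[[pat]]))
      }
      o <<- add_role(o, role_declaration(rc, domain = dom))
    } else {
      dom_set <- !is.null(o$roles[[rc]]$domain)
      for (pat in names(cfg$composite_domain_rules)) {
        if (grepl(pat, rc) && !dom_set) {
          o$roles[[rc]]$domain <<-
            ce_named(unname(cfg$composite_domain_rules[[pat]]))
        }
      }
    }
    ce_some(rc, filler)
  }

  namespaces <- character()
  for (di in seq_along(docs)) {
    doc <- docs[[di]]
    src <- paste0("doc", di)
    for (f in doc$terms) {
      if (isTRUE(f$is_obsolete)) next
      C <- ce_named(f$id)
      o <- add_class(o, f$id)
      if (!is.na(f$namespace)) namespaces[[f$id]] <- f$namespace
      if (!cfg$strip_asserted_isa) {
        for (d in f$is_a)
          o <- add_axiom(o, ax_subclass(C, ce_named(d)),
                         sprintf("%s:%d:is_a:%s", src, f$line, f$id))
      }
      for (e in f$relationship) {
        expr <- expand_relation(e[1L], e[2L], f$id, "relationship")
        o <- add_axiom(o, ax_subclass(C, expr),
                       sprintf("%s:%d:relationship:%s", src, f$line, f$id))
      }
      if (length(f$intersection_of) > 0L) {
        conjuncts <- lapply(f$intersection_of, function(e) {
          if (is.na(e[1L])) ce_named(e[2L])
          else expand_relation(e[1L], e[2L], f$id, "intersection_of")
        })
        o <- add_axiom(o, ax_equivalent(C, ce_and(conjuncts)),
                       sprintf("%s:%d:intersection_of:%s", src, f$line, f$id))
      }
      for (d in f$disjoint_from)
        o <- add_axiom(o, ax_disjoint(list(C, ce_named(d))),
                       sprintf("%s:%d:disjoint_from:%s", src, f$line, f$id))
    }
  }

  o <- assign_upper_roots(o, cfg$root_map, namespaces = namespaces,
                          mf_mode = cfg$mf_mode)
  if (cfg$add_quality_constraints) {
    qr <- cfg$quality_roots
    if (any(is.na(qr[c("process", "physical")])))
      stop("add_quality_constraints requires quality_roots$process and $physical")
    o <- add_quality_constraints(o, qr[["process"]], qr[["physical"]])
  }

  declared <- c(unlist(lapply(docs, function(d)
    c(names(d$terms), names(d$typedefs)))), unname(upper_classes()))
  dang <- dangling_references(docs)
  dang <- dang[!(dang$id %in% declared), , drop = FALSE]
  attr(o, "dangling") <- dang
  attr(o, "uses") <- if (length(uses) > 0L) do.call(rbind, uses) else
    data.frame(class = character(), relation = character(),
               target = character(), context = character(),
               use_index = integer(), stringsAsFactors = FALSE)
  attr(o, "typedef_conflicts") <- unlist(conflicts) %||% character()
  attr(o, "config") <- cfg
  attr(o, "docs") <- docs
  o
}

#' Align classes to the upper-level roots by identifier prefix
#'
#' Every named class whose prefix (the part of the identifier before
#' \code{":"}) appears in the root map receives a subclass axiom to the
#' mapped upper class.  GO-style entries mapped to \code{"namespace"} are
#' routed by the term's namespace: biological_process to Process,
#' cellular_component to Material object, molecular_function to Function
#' or Process depending on \code{mf_mode}.
#'
#' @param o a \code{dl_ontology}.
#' @param root_map named character vector (prefix -> upper class or
#'   \code{"namespace"}).
#' @param namespaces named character vector mapping term identifiers to
#'   their namespace tag (needed only for \code{"namespace"} routing).
#' @param mf_mode \code{"function"} or \code{"process"}.
#' @return the updated ontology.
#' @export
assign_upper_roots <- function(o, root_map, namespaces = character(),
                               mf_mode = "function") {
  stopifnot(inherits(o, "dl_ontology"))
  if (anyDuplicated(names(root_map)))
    stop("root_map assigns the same prefix twice")
  u <- upper_classes()
  existing <- vapply(o$axioms, axiom_key, "")
  for (id in setdiff(o$classes, unname(u))) {
    pfx <- term_prefix(id)
    if (is.na(pfx) || !(pfx %in% names(root_map))) next
    target <- unname(root_map[[pfx]])
    if (target == "namespace") {
      ns <- namespaces[id]
      if (is.na(ns)) next
      target <- switch(ns,
        biological_process = u[["process"]],
        cellular_component = u[["material"]],
        molecular_function = if (mf_mode == "function") u[["func"]]
                             else u[["process"]],
        NA_character_)
      if (is.na(target)) next
    }
    ax <- ax_subclass(ce_named(id), ce_named(target))
    if (!(axiom_key(ax) %in% existing)) {
      o <- add_axiom(o, ax, paste0("root:", pfx))
      existing <- c(existing, axiom_key(ax))
    }
  }
  o
}

#' Add the PATO quality constraints
#'
#' Qualities of processes must inhere in processes, and qualities of
#' physical objects must inhere in material objects:
#' \code{process_quality_root SubClassOf inheres_in only Process} and
#' \code{physical_quality_root SubClassOf inheres_in only MaterialObject}.
#' Applying the operation twice adds nothing (set semantics).
#'
#' @param o a \code{dl_ontology}.
#' @param process_quality_root,physical_quality_root identifiers of the
#'   two quality root classes; both must exist in the signature.
#' @return the updated ontology.
#' @export
add_quality_constraints <- function(o, process_quality_root,
                                    physical_quality_root) {
  stopifnot(inherits(o, "dl_ontology"))
  for (r in c(process_quality_root, physical_quality_root))
    if (!(r %in% o$classes)) stop("quality root not in signature: ", r)
  u <- upper_classes()
  axs <- list(
    ax_subclass(ce_named(process_quality_root),
                ce_only("inheres_in", ce_named(u[["process"]]))),
    ax_subclass(ce_named(physical_quality_root),
                ce_only("inheres_in", ce_named(u[["material"]]))))
  existing <- vapply(o$axioms, axiom_key, "")
  for (ax in axs) {
    if (!(axiom_key(ax) %in% existing))
      o <- add_axiom(o, ax, "quality_constraint")
  }
  o
}

# ---------------------------------------------------------------------------
# OWL 2 functional-style syntax export (for optional external checking)
# ---------------------------------------------------------------------------

owl_iri <- function(id) paste0(":", gsub("[^A-Za-z0-9_.-]", "_", id))

owl_ce <- function(e) {
  switch(e$op,
    named = owl_iri(e$id),
    top = "owl:Thing",
    bottom = "owl:Nothing",
    not = paste0("ObjectComplementOf(", owl_ce(e$arg), ")"),
    and = paste0("ObjectIntersectionOf(",
                 paste(vapply(e$args, owl_ce, ""), collapse = " "), ")"),
    or = paste0("ObjectUnionOf(",
                paste(vapply(e$args, owl_ce, ""), collapse = " "), ")"),
    some = paste0("ObjectSomeValuesFrom(", owl_iri(e$role), " ",
                  owl_ce(e$filler), ")"),
    only = paste0("ObjectAllValuesFrom(", owl_iri(e$role), " ",
                  owl_ce(e$filler), ")")
  )
}

#' Export an ontology as OWL 2 functional-style syntax
#'
#' Intended for cross-checking the built-in reasoner against an external
#' OWL reasoner; identifiers are mangled into a single default namespace.
#'
#' @param o a \code{dl_ontology}.
#' @param path output file path.
#' @return invisibly, the character vector of lines.
#' @export
write_owl_functional <- function(o, path = NULL) {
  stopifnot(inherits(o, "dl_ontology"))
  out <- c("Prefix(:=<http://example.org/ontoreason#>)",
           "Prefix(owl:=<http://www.w3.org/2002/07/owl#>)",
           "Ontology(<http://example.org/ontoreason>")
  for (cid in sort(o$classes))
    out <- c(out, paste0("Declaration(Class(", owl_iri(cid), "))"))
  for (r in names(o$roles))
    out <- c(out, paste0("Declaration(ObjectProperty(", owl_iri(r), "))"))
  for (r in names(o$roles)) {
    d <- o$roles[[r]]
    ri <- owl_iri(r)
    if (d$transitive) out <- c(out, paste0("TransitiveObjectProperty(", ri, ")"))
    if (d$reflexive) out <- c(out, paste0("ReflexiveObjectProperty(", ri, ")"))
    if (d$symmetric) out <- c(out, paste0("SymmetricObjectProperty(", ri, ")"))
    if (d$functional) out <- c(out, paste0("FunctionalObjectProperty(", ri, ")"))
    if (!is.na(d$inverse))
      out <- c(out, paste0("InverseObjectProperties(", ri, " ",
                           owl_iri(d$inverse), ")"))
    for (s in d$super_roles)
      out <- c(out, paste0("SubObjectPropertyOf(", ri, " ", owl_iri(s), ")"))
    if (!is.null(d$domain))
      out <- c(out, paste0("ObjectPropertyDomain(", ri, " ",
                           owl_ce(d$domain), ")"))
    if (!is.null(d$range))
      out <- c(out, paste0("ObjectPropertyRange(", ri, " ",
                           owl_ce(d$range), ")"))
  }
  for (ax in o$axioms) {
    out <- c(out, switch(ax$type,
      subclass = paste0("SubClassOf(", owl_ce(ax$sub), " ", owl_ce(ax$sup), ")"),
      equivalent = paste0("EquivalentClasses(", owl_ce(ax$a), " ",
                          owl_ce(ax$b), ")"),
      disjoint = paste0("DisjointClasses(",
                        paste(vapply(ax$members, owl_ce, ""), collapse = " "),
                        ")")))
  }
  out <- c(out, ")")
  if (!is.null(path)) writeLines(out, path, useBytes = TRUE)
  invisible(out)
}
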