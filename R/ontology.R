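#' @title Axioms, role declarations and the ontology container
#'
#' @description An ontology is a class signature, a role box (declarations
#'   with transitivity, reflexivity, symmetry, functionality, inverses,
#'   sub-role links and domain/range expressions) and a sequence of axioms
#'   (subclass, equivalence, disjointness), each carrying a provenance tag
#'   naming where it came from (file and line, generator, or an internal
#'   source such as the upper-level ontology).
#' @name dl_ontology
NULL

#' @rdname dl_axiom
#' @title Axiom constructors
#' @description \code{ax_subclass}, \code{ax_equivalent} and
#'   \code{ax_disjoint} build the three axiom variants.
#' @param sub,sup,a,b class expressions.
#' @return a \code{dl_axiom} object.
#' @export
ax_subclass <- function(sub, sup) {
  stopifnot(inherits(sub, "dl_ce"), inherits(sup, "dl_ce"))
  structure(list(type = "subclass", sub = sub, sup = sup), class = "dl_axiom")
}

#' @rdname dl_axiom
#' @export
ax_equivalent <- function(a, b) {
  stopifnot(inherits(a, "dl_ce"), inherits(b, "dl_ce"))
  structure(list(type = "equivalent", a = a, b = b), class = "dl_axiom")
}

#' @rdname dl_axiom
#' @param members list of at least two class expressions declared pairwise
#'   disjoint.
#' @export
ax_disjoint <- function(members) {
  stopifnot(is.list(members), length(members) >= 2L,
            all(vapply(members, inherits, TRUE, "dl_ce")))
  structure(list(type = "disjoint", members = members), class = "dl_axiom")
}

#' @export
format.dl_axiom <- function(x, ...) {
  switch(x$type,
    subclass = paste0(x$sub$k, " SubClassOf ", x$sup$k),
    equivalent = paste0(x$a$k, " EquivalentTo ", x$b$k),
    disjoint = paste0("DisjointClasses(",
                      paste(vapply(x$members, `[[`, "", "k"), collapse = ", "),
                      ")")
  )
}

#' @export
print.dl_axiom <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Declare a role (object property)
#'
#' @param id role identifier.
#' @param transitive,reflexive,symmetric,functional logical characteristic
#'   flags.
#' @param inverse identifier of the inverse role, or \code{NA}.
#' @param super_roles character vector of super-role identifiers.
#' @param domain,range optional class expressions; a \code{NULL} (or
#'   \code{Thing}) domain/range emits no axiom.
#' @return a \code{dl_role} declaration.
#' @export
role_declaration <- function(id, transitive = FALSE, reflexive = FALSE,
                             symmetric = FALSE, functional = FALSE,
                             inverse = NA_character_,
                             super_roles = character(),
                             domain = NULL, range = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.null(domain)) stopifnot(inherits(domain, "dl_ce"))
  if (!is.null(range)) stopifnot(inherits(range, "dl_ce"))
  structure(list(id = id, transitive = isTRUE(transitive),
                 reflexive = isTRUE(reflexive), symmetric = isTRUE(symmetric),
                 functional = isTRUE(functional),
                 inverse = as.character(inverse)[1L],
                 super_roles = unique(as.character(super_roles)),
                 domain = domain, range = range),
            class = "dl_role")
}

#' Create an empty ontology
#' @return a \code{dl_ontology} with empty signature, role box and axiom
#'   list.
#' @export
ontology <- function() {
  structure(list(classes = character(), roles = list(),
                 axioms = list(), provenance = character()),
            class = "dl_ontology")
}

#' @export
print.dl_ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d classes, %d roles, %d axioms\n",
              length(x$classes), length(x$roles), length(x$axioms)))
  invisible(x)
}

#' Add named classes to an ontology's signature
#' @param o a \code{dl_ontology}.
#' @param ids character vector of class identifiers.
#' @return the updated ontology.
#' @export
add_class <- function(o, ids) {
  stopifnot(inherits(o, "dl_ontology"))
  o$classes <- union(o$classes, ids)
  o
}

#' Add a role declaration to an ontology
#'
#' If the role declares an inverse, the inverse is declared too (created if
#' missing) and the inverse link is made symmetric, preserving the
#' role-box invariant that \code{inverse(inverse(r)) = r}.
#'
#' @param o a \code{dl_ontology}.
#' @param decl a \code{dl_role}.
#' @return the updated ontology.
#' @export
add_role <- function(o, decl) {
  stopifnot(inherits(o, "dl_ontology"), inherits(decl, "dl_role"))
  o$roles[[decl$id]] <- decl
  inv <- decl$inverse
  if (!is.na(inv)) {
    if (is.null(o$roles[[inv]]))
      o$roles[[inv]] <- role_declaration(inv, inverse = decl$id)
    else
      o$roles[[inv]]$inverse <- decl$id
  }
  o
}

#' Ensure a role exists, declaring a fresh primitive role if absent
#' @param o a \code{dl_ontology}.
#' @param id role identifier.
#' @return the updated ontology.
#' @export
ensure_role <- function(o, id) {
  if (is.null(o$roles[[id]])) o <- add_role(o, role_declaration(id))
  o
}

#' Append an axiom with provenance
#' @param o a \code{dl_ontology}.
#' @param ax a \code{dl_axiom}.
#' @param provenance a single string naming the axiom's source (e.g.
#'   \code{"file.obo:12:is_a"}, \code{"upper"}, \code{"root:PATO"}).
#' @return the updated ontology.
#' @export
add_axiom <- function(o, ax, provenance = "unspecified") {
  stopifnot(inherits(o, "dl_ontology"), inherits(ax, "dl_axiom"))
  o$axioms[[length(o$axioms) + 1L]] <- ax
  o$provenance <- c(o$provenance, provenance)
  exprs <- switch(ax$type,
    subclass = list(ax$sub, ax$sup),
    equivalent = list(ax$a, ax$b),
    disjoint = ax$members)
  for (e in exprs) {
    o <- add_class(o, ce_signature(e))
    for (r in ce_roles(e)) o <- ensure_role(o, r)
  }
  o
}

axiom_key <- function(ax) format(ax)

#' Normalize equivalence and disjointness axioms into subclass axioms
#'
#' \code{EquivalentClasses(a, b)} becomes the two inclusions
#' \code{a SubClassOf b} and \code{b SubClassOf a};
#' \code{DisjointClasses(m1, ..., mn)} becomes the n(n-1)/2 pairwise
#' axioms \code{(mi and mj) SubClassOf Nothing}.  Provenance of derived
#' axioms points to the original axiom's source.
#'
#' @param o a \code{dl_ontology}.
#' @return an ontology whose axioms are all of type \code{subclass}.
#' @export
normalize_axioms <- function(o) {
  stopifnot(inherits(o, "dl_ontology"))
  out <- o
  out$axioms <- list()
  out$provenance <- character()
  for (i in seq_along(o$axioms)) {
    ax <- o$axioms[[i]]
    prov <- o$provenance[[i]]
    if (ax$type == "subclass") {
      out <- add_axiom(out, ax, prov)
    } else if (ax$type == "equivalent") {
      out <- add_axiom(out, ax_subclass(ax$a, ax$b), prov)
      out <- add_axiom(out, ax_subclass(ax$b, ax$a), prov)
    } else {
      m <- ax$members
      n <- length(m)
      for (i1 in seq_len(n - 1L)) {
        for (i2 in seq.int(i1 + 1L, n)) {
          out <- add_axiom(out, ax_subclass(ce_and(m[[i1]], m[[i2]]),
                                            ce_bottom()), prov)
        }
      }
    }
  }
  out
}

#' Reflexive-transitive super-role closure
#'
#' Computes the set of roles implied to hold whenever \code{r} holds,
#' following declared sub-role links transitively and closing under
#' inverses (a super-role of the inverse contributes its own inverse).
#' Declared 2-cycles (\code{r} below \code{s} and \code{s} below \code{r})
#' are tolerated and reported via the \code{"equivalent_roles"} attribute.
#'
#' @param o a \code{dl_ontology}.
#' @param r a declared role identifier.
#' @return character vector of role identifiers including \code{r}
#'   itself, sorted; attribute \code{equivalent_roles} lists roles in the
#'   closure that also have \code{r} in theirs.
#' @export
super_roles_closure <- function(o, r) {
  stopifnot(inherits(o, "dl_ontology"))
  if (is.null(o$roles[[r]])) stop("unknown role: ", r)
  step <- function(set) {
    acc <- set
    for (s in set) {
      d <- o$roles[[s]]
      if (is.null(d)) next
      acc <- union(acc, intersect(d$super_roles, names(o$roles)))
      # closure under inverses: if s has inverse s- and s- is below t,
      # then s is below inverse(t)
      if (!is.na(d$inverse) && !is.null(o$roles[[d$inverse]])) {
        for (t in o$roles[[d$inverse]]$super_roles) {
          td <- o$roles[[t]]
          if (!is.null(td) && !is.na(td$inverse))
            acc <- union(acc, td$inverse)
        }
      }
    }
    acc
  }
  set <- r
  repeat {
    nxt <- step(set)
    if (length(nxt) == length(set)) break
    set <- nxt
  }
  set <- sort(set)
  eq <- character()
  for (s in setdiff(set, r)) {
    d <- o$roles[[s]]
    if (is.null(d)) next
    back <- s
    repeat {
      nxt <- unique(c(back, unlist(lapply(back, function(x) {
        dd <- o$roles[[x]]
        if (is.null(dd)) character() else intersect(dd$super_roles, names(o$roles))
      }))))
      if (length(nxt) == length(back)) break
      back <- nxt
    }
    if (r %in% back) eq <- c(eq, s)
  }
  attr(set, "equivalent_roles") <- sort(eq)
  set
}

#' Merge axioms and roles of several ontologies
#' @param ... \code{dl_ontology} objects.
#' @return a combined ontology; later role declarations override earlier
#'   ones with the same identifier.
#' @export
merge_ontologies <- function(...) {
  parts <- list(...)
  out <- ontology()
  for (p in parts) {
    stopifnot(inherits(p, "dl_ontology"))
    out$classes <- union(out$classes, p$classes)
    for (r in names(p$roles)) out$roles[[r]] <- p$roles[[r]]
    for (i in seq_along(p$axioms))
      out <- add_axiom(out, p$axioms[[i]], p$provenance[[i]])
  }
  out
}
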