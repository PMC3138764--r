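#' @title Reasoning services
#'
#' @description Higher-level operations built on the tableau engine:
#'   enumerating unsatisfiable named classes, testing subsumption,
#'   computing the classification (direct super-class graph over
#'   satisfiable equivalence classes) and answering class-expression
#'   subclass queries.
#' @name reasoning
NULL

#' Enumerate unsatisfiable named classes
#'
#' A named class is unsatisfiable when it can have no instances in any
#' model of the ontology -- the signature of a contradictory definition.
#'
#' @param o a \code{dl_ontology}.
#' @param prepared optional \code{\link{reasoner_prepare}} result.
#' @param ... passed to \code{\link{is_satisfiable}} (resource caps).
#' @return sorted character vector of unsatisfiable class identifiers;
#'   attribute \code{undecided} lists classes whose test hit a resource
#'   cap.
#' @export
unsatisfiable_classes <- function(o, prepared = NULL, ...) {
  stopifnot(inherits(o, "dl_ontology"))
  prep <- prepared %||% reasoner_prepare(o)
  unsat <- character()
  undecided <- character()
  for (cid in sort(o$classes)) {
    v <- is_satisfiable(o, ce_named(cid), prepared = prep, ...)
    if (is.na(v)) undecided <- c(undecided, cid)
    else if (!v) unsat <- c(unsat, cid)
  }
  attr(unsat, "undecided") <- undecided
  unsat
}

#' Test subsumption between class expressions
#'
#' \code{sub} is subsumed by \code{sup} (every instance of \code{sub} is
#' an instance of \code{sup}) exactly when \code{sub and not sup} is
#' unsatisfiable.
#'
#' @param o a \code{dl_ontology}.
#' @param sup,sub class expressions or Manchester-style strings.
#' @param prepared optional \code{\link{reasoner_prepare}} result.
#' @param ... passed to \code{\link{is_satisfiable}}.
#' @return \code{TRUE}, \code{FALSE} or \code{NA} (undecided).
#' @export
subsumes <- function(o, sup, sub, prepared = NULL, ...) {
  if (is.character(sup)) sup <- parse_class_expression(sup)
  if (is.character(sub)) sub <- parse_class_expression(sub)
  v <- is_satisfiable(o, ce_and(sub, ce_not(sup)), prepared = prepared, ...)
  if (is.na(v)) NA else !v
}

#' Classify an ontology
#'
#' Computes satisfiability for every named class and the full pairwise
#' subsumption relation among the satisfiable ones, groups mutually
#' subsuming classes into equivalence classes and reduces the subsumption
#' order to its direct (covering) edges.
#'
#' @param o a \code{dl_ontology}.
#' @param prepared optional \code{\link{reasoner_prepare}} result.
#' @param ... passed to \code{\link{is_satisfiable}}.
#' @return a \code{classification_index}: list with \code{classes},
#'   \code{satisfiable} (named logical), \code{unsatisfiable},
#'   \code{undecided}, \code{equivalents} (named list, class ->
#'   equivalent classes including itself), \code{direct_super} (named
#'   list over representatives) and the full \code{subsumption} logical
#'   matrix (\code{[i, j]} true when class i is subsumed by class j).
#' @export
classify <- function(o, prepared = NULL, ...) {
  stopifnot(inherits(o, "dl_ontology"))
  prep <- prepared %||% reasoner_prepare(o)
  ids <- sort(o$classes)
  sat <- logical(length(ids))
  names(sat) <- ids
  undecided <- character()
  for (cid in ids) {
    v <- is_satisfiable(o, ce_named(cid), prepared = prep, ...)
    if (is.na(v)) {
      undecided <- c(undecided, cid)
      sat[cid] <- NA
    } else sat[cid] <- v
  }
  live <- ids[which(sat)]
  n <- length(live)
  M <- matrix(FALSE, n, n, dimnames = list(live, live))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        M[i, j] <- TRUE
        next
      }
      v <- subsumes(o, ce_named(live[j]), ce_named(live[i]),
                    prepared = prep, ...)
      M[i, j] <- isTRUE(v)
    }
  }
  equivalents <- lapply(live, function(ci) live[M[ci, ] & M[, ci]])
  names(equivalents) <- live
  reps <- vapply(equivalents, function(g) sort(g)[1L], "")
  rep_ids <- sort(unique(reps))
  direct_super <- list()
  for (ri in rep_ids) {
    sups <- setdiff(rep_ids[M[ri, rep_ids]], ri)
    direct <- character()
    for (s in sups) {
      # s is direct unless some other strict super of ri lies below s
      others <- setdiff(sups, s)
      if (!any(M[others, s])) direct <- c(direct, s)
    }
    direct_super[[ri]] <- sort(direct)
  }
  structure(list(classes = ids, satisfiable = sat,
                 unsatisfiable = ids[which(!sat)], undecided = undecided,
                 equivalents = equivalents, direct_super = direct_super,
                 subsumption = M),
            class = "classification_index")
}

#' @export
print.classification_index <- function(x, ...) {
  cat(sprintf("<classification> %d classes, %d unsatisfiable, %d undecided\n",
              length(x$classes), length(x$unsatisfiable),
              length(x$undecided)))
  invisible(x)
}

#' Query for named subclasses of a class expression
#'
#' Returns the named classes subsumed by the query expression.
#' Unsatisfiable (Nothing-equivalent) classes are subclasses of
#' everything and are excluded unless requested.
#'
#' @param o a \code{dl_ontology}.
#' @param e a class expression or Manchester-style string.
#' @param include_unsatisfiable include Bottom-equivalent classes.
#' @param prepared optional \code{\link{reasoner_prepare}} result.
#' @param ... passed to \code{\link{is_satisfiable}}.
#' @return sorted character vector of class identifiers; attribute
#'   \code{undecided} lists classes whose test was undecided.
#' @export
query_subclasses <- function(o, e, include_unsatisfiable = FALSE,
                             prepared = NULL, ...) {
  if (is.character(e)) e <- parse_class_expression(e)
  prep <- prepared %||% reasoner_prepare(o)
  hits <- character()
  undecided <- character()
  for (cid in sort(o$classes)) {
    v <- subsumes(o, e, ce_named(cid), prepared = prep, ...)
    if (is.na(v)) {
      undecided <- c(undecided, cid)
      next
    }
    if (!v) next
    if (!include_unsatisfiable) {
      sv <- is_satisfiable(o, ce_named(cid), prepared = prep, ...)
      if (is.na(sv)) {
        undecided <- c(undecided, cid)
        next
      }
      if (!sv) next
    }
    hits <- c(hits, cid)
  }
  attr(hits, "undecided") <- undecided
  hits
}

#' Compute one minimal justification for an unsatisfiable class
#'
#' Deletion-based shrinking: walk the axiom list once, dropping every
#' axiom whose removal keeps the class unsatisfiable.  The result is
#' subset-minimal (removing any member restores satisfiability); it is
#' one justification, not an enumeration of all of them.  Role-box
#' declarations (domain, range, functionality, ...) are part of the
#' background and are not shrunk.
#'
#' @param o a \code{dl_ontology}.
#' @param cid identifier of an unsatisfiable class.
#' @param ... passed to \code{\link{is_satisfiable}}.
#' @return a list with \code{axioms} (list of \code{dl_axiom}) and
#'   \code{provenance} (character vector naming each axiom's source).
#' @export
justify <- function(o, cid, ...) {
  stopifnot(inherits(o, "dl_ontology"))
  target <- ce_named(cid)
  test_unsat <- function(idx) {
    sub <- o
    sub$axioms <- o$axioms[idx]
    sub$provenance <- o$provenance[idx]
    v <- is_satisfiable(sub, target, ...)
    if (is.na(v)) stop("justification undecided for ", cid)
    !v
  }
  if (!test_unsat(seq_along(o$axioms)))
    stop("class is satisfiable, nothing to justify: ", cid)
  keep <- seq_along(o$axioms)
  for (i in seq_along(o$axioms)) {
    cand <- setdiff(keep, i)
    if (test_unsat(cand)) keep <- cand
  }
  list(axioms = o$axioms[keep], provenance = o$provenance[keep])
}

# ---------------------------------------------------------------------------
# Brute-force finite-model search: the independent oracle
# ---------------------------------------------------------------------------

oracle_compiled <- function(o) {
  on <- normalize_axioms(o)
  constraints <- list()
  for (ax in on$axioms)
    constraints[[length(constraints) + 1L]] <-
      ce_or(nnf(ce_not(ax$sub)), nnf(ax$sup))
  for (r in names(o$roles)) {
    d <- o$roles[[r]]
    if (!is.null(d$domain) && d$domain$op != "top")
      constraints[[length(constraints) + 1L]] <-
        ce_or(ce_only(r, ce_bottom()), nnf(d$domain))
    if (!is.null(d$range) && d$range$op != "top")
      constraints[[length(constraints) + 1L]] <- ce_only(r, nnf(d$range))
  }
  constraints
}

#' Exhaustive finite-model satisfiability check
#'
#' A deliberately independent decision procedure used to cross-check the
#' tableau engine: grounds the ontology over candidate domains of size 1
#' to \code{max_domain} -- class-membership and role atoms become
#' propositional variables, existential and universal restrictions
#' become finite disjunctions and conjunctions over the domain, and the
#' role box (hierarchy, transitivity, reflexivity, symmetry, inverses,
#' functionality) becomes ground clauses -- and decides each grounding
#' with a small DPLL procedure (Tseitin-style clausification, unit
#' propagation, chronological backtracking).  In the
#' ALC-plus-transitive-roles fragment, which has small models at this
#' problem scale, exhausting the domain bound is treated as
#' unsatisfiability.
#'
#' @param o a \code{dl_ontology}.
#' @param e a class expression or Manchester-style string that must be
#'   inhabited (by domain element 1).
#' @param max_domain largest domain size searched (default 4).
#' @return \code{TRUE} if a model of size at most \code{max_domain}
#'   exists, otherwise \code{FALSE}.
#' @export
model_check_satisfiable <- function(o, e, max_domain = 4) {
  if (is.character(e)) e <- parse_class_expression(e)
  stopifnot(inherits(e, "dl_ce"))
  constraints <- oracle_compiled(o)
  goal <- nnf(e)
  class_ids <- sort(unique(c(o$classes,
                             unlist(lapply(constraints, ce_signature)),
                             ce_signature(goal))))
  role_ids <- sort(unique(c(names(o$roles),
                            unlist(lapply(constraints, ce_roles)),
                            ce_roles(goal))))
  for (n in seq_len(max_domain)) {
    if (oracle_search(o, constraints, goal, class_ids, role_ids, n))
      return(TRUE)
  }
  FALSE
}

oracle_search <- function(o, constraints, goal, class_ids, role_ids, n) {
  nc <- length(class_ids)
  nr <- length(role_ids)
  # atom numbering: class atoms first, then role atoms
  catom <- function(ci, i) (match(ci, class_ids) - 1L) * n + i
  ratom <- function(r, i, j)
    nc * n + (match(r, role_ids) - 1L) * n * n + (i - 1L) * n + j

  n_atoms <- nc * n + nr * n * n
  next_var <- n_atoms
  clauses <- list()
  emit <- function(cl) clauses[[length(clauses) + 1L]] <<- as.integer(cl)

  # clausify a grounded NNF expression at element i; returns a literal.
  # Full Tseitin (biconditional) encoding: once the real atoms are
  # assigned, unit propagation forces every auxiliary variable, so the
  # search below only ever branches on real atoms.
  tseitin_and <- function(lits) {
    next_var <<- next_var + 1L
    a <- next_var
    for (l in lits) emit(c(-a, l))
    emit(c(a, -lits))
    a
  }
  tseitin_or <- function(lits) {
    next_var <<- next_var + 1L
    a <- next_var
    emit(c(-a, lits))
    for (l in lits) emit(c(a, -l))
    a
  }
  ground_lit <- function(e, i) {
    switch(e$op,
      named = catom(e$id, i),
      not = -catom(e$arg$id, i),
      top = {
        next_var <<- next_var + 1L
        emit(next_var)          # forced true
        next_var
      },
      bottom = {
        next_var <<- next_var + 1L
        emit(-next_var)         # forced false
        next_var
      },
      and = tseitin_and(vapply(e$args, ground_lit, 0L, i = i)),
      or = tseitin_or(vapply(e$args, ground_lit, 0L, i = i)),
      some = tseitin_or(vapply(seq_len(n), function(j)
        tseitin_and(c(ratom(e$role, i, j), ground_lit(e$filler, j))),
        0L)),
      only = tseitin_and(vapply(seq_len(n), function(j)
        tseitin_or(c(-ratom(e$role, i, j), ground_lit(e$filler, j))),
        0L)),
      stop("unexpected op in grounded expression: ", e$op)
    )
  }

  for (cn in constraints) for (i in seq_len(n)) emit(ground_lit(cn, i))
  emit(ground_lit(goal, 1L))

  for (r in role_ids) {
    d <- o$roles[[r]]
    if (is.null(d)) next
    if (d$reflexive) for (i in seq_len(n)) emit(ratom(r, i, i))
    if (d$transitive) {
      for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
        emit(c(-ratom(r, i, j), -ratom(r, j, k), ratom(r, i, k)))
    }
    if (d$functional && n > 1L) {
      for (i in seq_len(n)) {
        for (j in seq_len(n - 1L)) for (k in seq.int(j + 1L, n))
          emit(c(-ratom(r, i, j), -ratom(r, i, k)))
      }
    }
    for (s in intersect(d$super_roles, role_ids)) {
      for (i in seq_len(n)) for (j in seq_len(n))
        emit(c(-ratom(r, i, j), ratom(s, i, j)))
    }
    ir <- if (!is.na(d$inverse) && d$inverse %in% role_ids) d$inverse
          else if (d$symmetric) r else NULL
    if (!is.null(ir)) {
      for (i in seq_len(n)) for (j in seq_len(n))
        emit(c(-ratom(r, i, j), ratom(ir, j, i)))
    }
  }

  dpll_sat(clauses, next_var, n_real = n_atoms)
}

# minimal DPLL: unit propagation + chronological backtracking; branching
# is restricted to the first n_real variables (the ground class and role
# atoms) -- the Tseitin auxiliaries are forced by propagation once the
# real atoms are decided
dpll_sat <- function(clauses, n_vars, n_real = n_vars) {
  vals <- integer(n_vars)  # 0 unknown, 1 true, -1 false

  propagate <- function(vals) {
    repeat {
      changed <- FALSE
      for (cl in clauses) {
        sat <- FALSE
        unassigned <- integer()
        for (l in cl) {
          v <- vals[abs(l)]
          if (v == 0L) unassigned <- c(unassigned, l)
          else if (v == sign(l)) {
            sat <- TRUE
            break
          }
        }
        if (sat) next
        if (length(unassigned) == 0L) return(NULL)   # conflict
        if (length(unassigned) == 1L) {
          l <- unassigned[[1L]]
          vals[abs(l)] <- sign(l)
          changed <- TRUE
        }
      }
      if (!changed) return(vals)
    }
  }

  # branch on a real atom from a shortest unresolved clause, trying the
  # polarity that satisfies that clause first; real atoms not occurring
  # in any unresolved clause are irrelevant and left unassigned
  choose_var <- function(vals) {
    best <- NULL
    best_len <- Inf
    any_unresolved <- FALSE
    for (cl in clauses) {
      sat <- FALSE
      unassigned <- integer()
      for (l in cl) {
        v <- vals[abs(l)]
        if (v == 0L) unassigned <- c(unassigned, l)
        else if (v == sign(l)) {
          sat <- TRUE
          break
        }
      }
      if (sat || length(unassigned) == 0L) next
      any_unresolved <- TRUE
      real <- unassigned[abs(unassigned) <= n_real]
      if (length(real) > 0L && length(unassigned) < best_len) {
        best <- real[[1L]]
        best_len <- length(unassigned)
        if (best_len <= 2L) break
      }
    }
    list(lit = best, open = any_unresolved)
  }

  # failed-literal probing over the real atoms: if one polarity of an
  # atom already conflicts under unit propagation, fix the other.
  # Collapses the frequent pattern of pairwise-contradictory binary
  # clauses (e.g. an unsatisfiable named class) without search.
  probe <- function(vals) {
    repeat {
      vals <- propagate(vals)
      if (is.null(vals)) return(NULL)
      changed <- FALSE
      for (v in seq_len(min(n_real, n_vars))) {
        if (vals[v] != 0L) next
        for (sgn in c(1L, -1L)) {
          trial <- vals
          trial[v] <- sgn
          if (is.null(propagate(trial))) {
            vals[v] <- -sgn
            changed <- TRUE
            break
          }
        }
      }
      if (!changed) return(vals)
    }
  }

  search <- function(vals) {
    vals <- propagate(vals)
    if (is.null(vals)) return(FALSE)
    ch <- choose_var(vals)
    if (!ch$open) return(TRUE)    # every clause satisfied
    if (is.null(ch$lit)) {
      # unresolved clauses but no free real atoms: with the full
      # Tseitin encoding propagation decides the rest; if anything is
      # still open here the remaining auxiliaries admit any value
      # consistent with propagation, so pick the first free one
      free <- which(vals == 0L)
      if (length(free) == 0L) return(TRUE)
      v <- free[[1L]]
      for (sgn in c(1L, -1L)) {
        trial <- vals
        trial[v] <- sgn
        if (search(trial)) return(TRUE)
      }
      return(FALSE)
    }
    v <- abs(ch$lit)
    for (sgn in c(sign(ch$lit), -sign(ch$lit))) {
      trial <- vals
      trial[v] <- sgn
      if (search(trial)) return(TRUE)
    }
    FALSE
  }

  vals <- probe(vals)
  if (is.null(vals)) return(FALSE)
  search(vals)
}
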