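#' @title Tableau satisfiability engine
#'
#' @description Decides class-expression satisfiability with respect to an
#'   ontology by building a completion graph: nodes carry label sets of
#'   NNF expressions, edges carry role sets.  The calculus covers ALC plus
#'   role hierarchies, inverse roles, transitive roles (universal-
#'   restriction propagation), functional roles (successor merging,
#'   oldest node wins), reflexive roles (every node is a self-neighbour
#'   for them) and general concept inclusions by internalization: every
#'   node receives \code{not C or D} for each normalized axiom
#'   \code{C SubClassOf D}.  Termination is enforced by pairwise
#'   (equality) blocking and by resource caps; exceeding a cap yields an
#'   explicit \code{NA} ("undecided"), never a silent answer.
#' @name tableau
NULL

# content-addressed caches: negation keys and disjunct metadata are pure
# functions of an expression's canonical form, so they are memoized
# package-wide
.ts_memo <- new.env(parent = emptyenv())
.ts_memo$neg <- new.env(parent = emptyenv())
.ts_memo$or <- new.env(parent = emptyenv())

ts_neg_expr <- function(e) {
  k <- e$k
  v <- get0(k, .ts_memo$neg)
  if (!is.null(v)) return(v)
  v <- nnf(ce_not(e))
  assign(k, v, .ts_memo$neg)
  v
}

ts_neg_key <- function(e) ts_neg_expr(e)$k

ts_or_meta <- function(e) {
  k <- e$k
  v <- get0(k, .ts_memo$or)
  if (!is.null(v)) return(v)
  # least-commitment branch order: literals before universal
  # restrictions before conjunction/disjunctions before existentials
  # (which create successors); deterministic within each tier
  rank <- vapply(e$args, function(a)
    switch(a$op, named = 1L, not = 1L, bottom = 1L, top = 1L,
           only = 2L, and = 3L, or = 3L, some = 4L), 0L)
  ord <- order(rank, seq_along(e$args))
  v <- list(args = e$args[ord],
            argks = vapply(e$args[ord], `[[`, "", "k"),
            negks = vapply(e$args[ord], ts_neg_key, ""))
  assign(k, v, .ts_memo$or)
  v
}

ts_cap_condition <- function(what) {
  structure(class = c("ts_cap", "condition"),
            list(message = paste0("reasoner resource cap exceeded: ", what),
                 call = NULL))
}

#' Precompile an ontology for repeated satisfiability tests
#'
#' Normalizes axioms into subclass form and splits them into (a)
#' absorbed axioms -- those whose left-hand side is a named class, or an
#' intersection containing one, which fire lazily when the trigger class
#' enters a node label (standard lazy unfolding; equivalent to
#' internalization but without the useless branching on nodes the axiom
#' cannot affect) -- and (b) residual general inclusions, internalized as
#' NNF disjunctions added to every node.  Role domain and range
#' restrictions become deterministic edge rules (\code{r(x, y)} adds the
#' domain class at \code{x} and the range class at \code{y}).  The role
#' box is tabulated: super-role closures, inverses, transitivity,
#' functionality, reflexivity.
#'
#' @param o a \code{dl_ontology}.
#' @return an opaque prepared object accepted by the \code{prepared}
#'   argument of \code{\link{is_satisfiable}} and friends.
#' @export
reasoner_prepare <- function(o) {
  stopifnot(inherits(o, "dl_ontology"))
  on <- normalize_axioms(o)
  tbox <- list()
  seen <- character()
  absorbed <- new.env(parent = emptyenv())
  push <- function(e) {
    if (e$op == "top") return()
    if (!(e$k %in% seen)) {
      seen <<- c(seen, e$k)
      tbox[[length(tbox) + 1L]] <<- e
    }
  }
  absorb <- function(trigger, e) {
    if (e$op == "top") return()
    cur <- get0(trigger, absorbed)
    if (!is.null(cur) && e$k %in% vapply(cur, `[[`, "", "k")) return()
    assign(trigger, c(cur, list(e)), absorbed)
  }
  for (ax in on$axioms) {
    sub <- ax$sub
    sup_e <- nnf(ax$sup)
    if (sub$op == "named") {
      absorb(sub$id, sup_e)
    } else if (sub$op == "and" &&
               any(vapply(sub$args, `[[`, "", "op") == "named")) {
      i <- which(vapply(sub$args, `[[`, "", "op") == "named")[1L]
      trigger <- sub$args[[i]]$id
      rest <- sub$args[-i]
      absorb(trigger, ce_or(c(lapply(rest, function(x) nnf(ce_not(x))),
                              list(sup_e))))
    } else {
      push(ce_or(nnf(ce_not(sub)), sup_e))
    }
  }
  domain <- list()
  range <- list()
  for (r in names(o$roles)) {
    d <- o$roles[[r]]
    if (!is.null(d$domain) && d$domain$op != "top")
      domain[[r]] <- nnf(d$domain)
    if (!is.null(d$range) && d$range$op != "top")
      range[[r]] <- nnf(d$range)
  }
  sup <- list()
  for (r in names(o$roles)) {
    cl <- super_roles_closure(o, r)
    attributes(cl) <- NULL
    sup[[r]] <- cl
  }
  inv <- vapply(o$roles, function(d) {
    if (!is.na(d$inverse)) d$inverse
    else if (d$symmetric) d$id
    else NA_character_
  }, "")
  trans <- names(o$roles)[vapply(o$roles, `[[`, TRUE, "transitive")]
  refl <- names(o$roles)[vapply(o$roles, `[[`, TRUE, "reflexive")]
  refl_all <- unique(unlist(sup[refl]))
  fun <- names(o$roles)[vapply(o$roles, `[[`, TRUE, "functional")]
  # without inverse or functional roles (the ALC+transitive fragment),
  # subset "anywhere" blocking is sound and collapses the completion
  # tree much earlier than pairwise ancestor blocking
  anywhere <- length(fun) == 0L && all(is.na(inv))
  structure(list(tbox = tbox, absorbed = absorbed, domain = domain,
                 range = range, sup = sup, inv = inv, trans = trans,
                 refl_all = refl_all %||% character(), fun = fun,
                 anywhere = anywhere,
                 up_cache = new.env(parent = emptyenv())),
            class = "reasoner_prepared")
}

ts_up <- function(prep, roles) {
  key <- paste(roles, collapse = "\r")
  v <- get0(key, prep$up_cache)
  if (!is.null(v)) return(v)
  out <- character()
  for (r in roles) {
    cl <- prep$sup[[r]]
    out <- c(out, if (is.null(cl)) r else cl)
  }
  out <- unique(out)
  assign(key, out, prep$up_cache)
  out
}

ts_new_state <- function() {
  list(counter = 2L, nodes = list(), edges = list(), clash = FALSE)
}

ts_new_node <- function(parent = NA_character_,
                        parent_roles = character()) {
  list(label = list(), parent = parent, parent_roles = parent_roles,
       queue = character(), somes = character(), onlys = character(),
       ors = character())
}

ts_order <- function(st) {
  ids <- names(st$nodes)
  ids[order(as.integer(sub("^n", "", ids)))]
}

add_to_label <- function(st, nid, e) {
  node <- st$nodes[[nid]]
  if (is.null(node)) return(st)
  k <- e$k
  if (k %in% names(node$label)) return(st)
  if (e$op == "bottom") {
    st$clash <- TRUE
    return(st)
  }
  if (e$op == "top") return(st)
  if (e$op == "not" && e$arg$k %in% names(node$label)) {
    st$clash <- TRUE
    return(st)
  }
  if (e$op == "named" && paste0("(not ", k, ")") %in% names(node$label)) {
    st$clash <- TRUE
    return(st)
  }
  node$label[[k]] <- e
  node$queue <- c(node$queue, k)
  st$nodes[[nid]] <- node
  st
}

# neighbours of x as list(id=, roles=) entries; roles are up-closed
ts_neighbours <- function(st, prep, x) {
  res <- list()
  for (ed in st$edges) {
    if (ed$from == x)
      res[[length(res) + 1L]] <- list(id = ed$to, roles = ts_up(prep, ed$roles))
    if (ed$to == x) {
      ir <- prep$inv[ed$roles]
      ir <- ir[!is.na(ir)]
      if (length(ir) > 0L)
        res[[length(res) + 1L]] <- list(id = ed$from,
                                        roles = ts_up(prep, ir))
    }
  }
  if (length(prep$refl_all) > 0L)
    res[[length(res) + 1L]] <- list(id = x, roles = prep$refl_all)
  res
}

ts_apply_only <- function(st, prep, x, e) {
  trans <- prep$trans
  for (nb in ts_neighbours(st, prep, x)) {
    if (is.null(st$nodes[[nb$id]])) next
    if (e$role %in% nb$roles) {
      st <- add_to_label(st, nb$id, e$filler)
      if (st$clash) return(st)
    }
    if (length(trans) > 0L) {
      for (s in trans) {
        if (!(s %in% nb$roles)) next
        clos <- prep$sup[[s]]
        if (!is.null(clos) && e$role %in% clos) {
          st <- add_to_label(st, nb$id, ce_only(s, e$filler))
          if (st$clash) return(st)
        }
      }
    }
  }
  st
}

# re-fire the universal restrictions of the given nodes (used after edge
# creation or node merging, when new neighbour relationships appear)
ts_apply_onlys_at <- function(st, prep, ids) {
  for (nid in unique(ids)) {
    node <- st$nodes[[nid]]
    if (is.null(node)) next
    for (k in node$onlys) {
      st <- ts_apply_only(st, prep, nid, node$label[[k]])
      if (st$clash) return(st)
    }
  }
  st
}

ts_adjacent <- function(st, x) {
  out <- character()
  for (ed in st$edges) {
    if (ed$from == x) out <- c(out, ed$to)
    if (ed$to == x) out <- c(out, ed$from)
  }
  unique(out)
}

ts_functional_violation <- function(st, prep) {
  if (length(prep$fun) == 0L) return(NULL)
  for (nid in ts_order(st)) {
    nbs <- ts_neighbours(st, prep, nid)
    for (f in prep$fun) {
      ids <- unique(unlist(lapply(nbs, function(nb)
        if (f %in% nb$roles) nb$id else NULL)))
      if (length(ids) >= 2L) {
        num <- as.integer(sub("^n", "", ids))
        o <- order(num)
        return(list(target = ids[o[1L]], victim = ids[o[2L]]))
      }
    }
  }
  NULL
}

ts_merge <- function(st, prep, target, victim) {
  if (target == victim) return(st)
  vict <- st$nodes[[victim]]
  for (k in names(vict$label)) {
    st <- add_to_label(st, target, vict$label[[k]])
    if (st$clash) return(st)
  }
  # rewrite edges, combining duplicates
  combined <- list()
  for (ed in st$edges) {
    f <- if (ed$from == victim) target else ed$from
    t <- if (ed$to == victim) target else ed$to
    key <- paste0(f, "->", t)
    if (is.null(combined[[key]]))
      combined[[key]] <- list(from = f, to = t, roles = ed$roles)
    else
      combined[[key]]$roles <- unique(c(combined[[key]]$roles, ed$roles))
  }
  st$edges <- unname(combined)
  for (nid in names(st$nodes)) {
    if (identical(st$nodes[[nid]]$parent, victim))
      st$nodes[[nid]]$parent <- target
  }
  st$nodes[[victim]] <- NULL
  ts_apply_onlys_at(st, prep, c(target, ts_adjacent(st, target)))
}

ts_drain <- function(st, prep, ctl) {
  repeat {
    progressed <- FALSE
    for (nid in ts_order(st)) {
      if (is.null(st$nodes[[nid]])) next
      repeat {
        node <- st$nodes[[nid]]
        if (is.null(node) || length(node$queue) == 0L) break
        k <- node$queue[[1L]]
        st$nodes[[nid]]$queue <- node$queue[-1L]
        e <- node$label[[k]]
        progressed <- TRUE
        if (e$op == "and") {
          for (a in e$args) {
            st <- add_to_label(st, nid, a)
            if (st$clash) return(st)
          }
        } else if (e$op == "or") {
          st$nodes[[nid]]$ors <- union(st$nodes[[nid]]$ors, k)
        } else if (e$op == "some") {
          st$nodes[[nid]]$somes <- union(st$nodes[[nid]]$somes, k)
        } else if (e$op == "only") {
          st$nodes[[nid]]$onlys <- union(st$nodes[[nid]]$onlys, k)
          st <- ts_apply_only(st, prep, nid, e)
          if (st$clash) return(st)
        } else if (e$op == "named") {
          trigs <- get0(e$id, prep$absorbed)
          if (!is.null(trigs)) {
            for (t in trigs) {
              st <- add_to_label(st, nid, t)
              if (st$clash) return(st)
            }
          }
        }
      }
    }
    viol <- ts_functional_violation(st, prep)
    if (!is.null(viol)) {
      st <- ts_merge(st, prep, viol$target, viol$victim)
      if (st$clash) return(st)
      progressed <- TRUE
    }
    if (!progressed) break
  }
  st
}

ts_some_satisfied <- function(st, prep, nid, e) {
  for (nb in ts_neighbours(st, prep, nid)) {
    y <- st$nodes[[nb$id]]
    if (is.null(y)) next
    if (!(e$role %in% nb$roles)) next
    if (e$filler$op == "top" || e$filler$k %in% names(y$label)) return(TRUE)
  }
  FALSE
}

ts_label_sig <- function(node) paste(sort(names(node$label)), collapse = "\r")

ts_is_blocked <- function(st, x, memo, prep) {
  if (!is.null(memo[[x]])) return(memo[[x]])
  # node is blocked if it or any ancestor is directly blocked
  chain <- character()
  cur <- x
  seen <- character()
  while (!is.na(cur) && !(cur %in% seen)) {
    seen <- c(seen, cur)
    chain <- c(chain, cur)
    cur <- st$nodes[[cur]]$parent
    if (is.null(cur)) cur <- NA_character_
  }
  blocked <- FALSE
  for (z in chain) {
    hit <- if (prep$anywhere) ts_subset_blocked(st, z)
           else ts_directly_blocked(st, z)
    if (hit) {
      blocked <- TRUE
      break
    }
  }
  memo[[x]] <- blocked
  blocked
}

# subset anywhere blocking: x is blocked by any earlier-created node
# whose label includes x's (sound without inverse/functional roles)
ts_subset_blocked <- function(st, x) {
  node <- st$nodes[[x]]
  if (is.na(node$parent)) return(FALSE)
  lx <- names(node$label)
  xnum <- as.integer(sub("^n", "", x))
  for (y in ts_order(st)) {
    if (as.integer(sub("^n", "", y)) >= xnum) break
    if (all(lx %in% names(st$nodes[[y]]$label))) return(TRUE)
  }
  FALSE
}

ts_directly_blocked <- function(st, x) {
  node <- st$nodes[[x]]
  px <- node$parent
  if (is.na(px) || is.null(st$nodes[[px]])) return(FALSE)
  lx <- ts_label_sig(node)
  lpx <- ts_label_sig(st$nodes[[px]])
  rx <- paste(sort(node$parent_roles), collapse = "\r")
  # candidate witnesses: strict ancestors of x that themselves have a parent
  seen <- c(x)
  y <- px
  while (!is.na(y) && !(y %in% seen)) {
    seen <- c(seen, y)
    yn <- st$nodes[[y]]
    if (is.null(yn)) break
    py <- yn$parent
    if (!is.na(py) && !is.null(st$nodes[[py]])) {
      if (identical(ts_label_sig(yn), lx) &&
          identical(ts_label_sig(st$nodes[[py]]), lpx) &&
          identical(paste(sort(yn$parent_roles), collapse = "\r"), rx))
        return(TRUE)
    }
    y <- if (is.null(py)) NA_character_ else py
  }
  FALSE
}

ts_choose <- function(st, prep) {
  branch <- NULL
  for (nid in ts_order(st)) {
    node <- st$nodes[[nid]]
    if (length(node$ors) > 0L) {
      lbl <- names(node$label)
      drop <- character()
      for (k in node$ors) {
        m <- ts_or_meta(node$label[[k]])
        if (any(m$argks %in% lbl)) {
          # satisfied; label sets only grow along a branch, so the
          # disjunction stays satisfied in every descendant state
          drop <- c(drop, k)
          next
        }
        open <- which(!(m$negks %in% lbl))
        if (length(open) == 0L)
          return(list(act = list(type = "clash"), st = st))
        if (length(open) == 1L)
          return(list(act = list(type = "unit", nid = nid,
                                 expr = m$args[[open]]), st = st))
        if (is.null(branch) || length(open) < length(branch$open))
          branch <- list(type = "branch", nid = nid, open = m$args[open])
      }
      if (length(drop) > 0L)
        st$nodes[[nid]]$ors <- setdiff(node$ors, drop)
    }
  }
  if (!is.null(branch)) return(list(act = branch, st = st))
  memo <- new.env(parent = emptyenv())
  for (nid in ts_order(st)) {
    node <- st$nodes[[nid]]
    if (length(node$somes) == 0L) next
    if (ts_is_blocked(st, nid, memo, prep)) next
    for (k in node$somes) {
      e <- node$label[[k]]
      if (!ts_some_satisfied(st, prep, nid, e))
        return(list(act = list(type = "some", nid = nid, expr = e),
                    st = st))
    }
  }
  list(act = list(type = "sat"), st = st)
}

ts_make_successor <- function(st, prep, ctl, x, e) {
  ctl$nodes <- ctl$nodes + 1L
  if (ctl$nodes > ctl$max_nodes) stop(ts_cap_condition("nodes"))
  id <- paste0("n", st$counter)
  st$counter <- st$counter + 1L
  st$nodes[[id]] <- ts_new_node(parent = x, parent_roles = e$role)
  st$edges[[length(st$edges) + 1L]] <- list(from = x, to = id,
                                            roles = e$role)
  st <- add_to_label(st, id, e$filler)
  if (st$clash) return(st)
  for (tb in prep$tbox) {
    st <- add_to_label(st, id, tb)
    if (st$clash) return(st)
  }
  st <- ts_apply_edge_rules(st, prep, x, id, e$role)
  if (st$clash) return(st)
  ts_apply_onlys_at(st, prep, c(x, id))
}

# domain/range rules: r(x, y) adds domain(s) at x and range(s) at y for
# every implied super-role s, and symmetrically through the inverses
ts_apply_edge_rules <- function(st, prep, from, to, roles) {
  for (s in ts_up(prep, roles)) {
    d <- prep$domain[[s]]
    if (!is.null(d)) {
      st <- add_to_label(st, from, d)
      if (st$clash) return(st)
    }
    rg <- prep$range[[s]]
    if (!is.null(rg)) {
      st <- add_to_label(st, to, rg)
      if (st$clash) return(st)
    }
    iv <- if (s %in% names(prep$inv)) prep$inv[[s]] else NA_character_
    if (!is.na(iv)) {
      d2 <- prep$domain[[iv]]
      if (!is.null(d2)) {
        st <- add_to_label(st, to, d2)
        if (st$clash) return(st)
      }
      rg2 <- prep$range[[iv]]
      if (!is.null(rg2)) {
        st <- add_to_label(st, from, rg2)
        if (st$clash) return(st)
      }
    }
  }
  st
}

ts_run <- function(st, prep, ctl) {
  repeat {
    st <- ts_drain(st, prep, ctl)
    if (st$clash) return(FALSE)
    ch <- ts_choose(st, prep)
    act <- ch$act
    st <- ch$st
    if (act$type == "sat") return(TRUE)
    if (act$type == "clash") return(FALSE)
    if (act$type == "unit") {
      st <- add_to_label(st, act$nid, act$expr)
      if (st$clash) return(FALSE)
      next
    }
    if (act$type == "branch") {
      for (d in act$open) {
        ctl$branches <- ctl$branches + 1L
        if (ctl$branches > ctl$max_branches) stop(ts_cap_condition("branches"))
        st2 <- add_to_label(st, act$nid, d)
        r <- if (st2$clash) FALSE else ts_run(st2, prep, ctl)
        if (isTRUE(r)) return(TRUE)
        # semantic branching: the disjunct failed, so its negation holds
        # in every remaining alternative of this choice point
        st <- add_to_label(st, act$nid, ts_neg_expr(d))
        if (st$clash) return(FALSE)
      }
      return(FALSE)
    }
    if (act$type == "some") {
      st <- ts_make_successor(st, prep, ctl, act$nid, act$expr)
      if (st$clash) return(FALSE)
      next
    }
    stop("internal: unknown tableau action")
  }
}

#' Decide class-expression satisfiability
#'
#' @param o a \code{dl_ontology}.
#' @param e a class expression (\code{dl_ce}) or a Manchester-style
#'   string; fresh names not in the signature are treated as
#'   unconstrained.
#' @param prepared optionally, the result of
#'   \code{\link{reasoner_prepare}(o)} to amortize preprocessing over
#'   many calls.
#' @param max_nodes,max_branches resource caps; when exceeded the answer
#'   is \code{NA} ("undecided").
#' @return \code{TRUE} (a model exists), \code{FALSE} (unsatisfiable) or
#'   \code{NA} (resource cap exceeded).
#' @export
is_satisfiable <- function(o, e, prepared = NULL,
                           max_nodes = 1e5, max_branches = 1e5) {
  if (is.character(e)) e <- parse_class_expression(e)
  stopifnot(inherits(e, "dl_ce"))
  prep <- prepared %||% reasoner_prepare(o)
  ctl <- new.env(parent = emptyenv())
  ctl$nodes <- 1L
  ctl$branches <- 0L
  ctl$max_nodes <- max_nodes
  ctl$max_branches <- max_branches
  st <- ts_new_state()
  st$nodes[["n1"]] <- ts_new_node()
  st <- add_to_label(st, "n1", nnf(e))
  if (!st$clash) {
    for (tb in prep$tbox) {
      st <- add_to_label(st, "n1", tb)
      if (st$clash) break
    }
  }
  if (st$clash) return(FALSE)
  tryCatch(ts_run(st, prep, ctl),
           ts_cap = function(c) NA)
}
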