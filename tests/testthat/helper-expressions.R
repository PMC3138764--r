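# shared helpers: seeded random expressions and a tiny in-code ontology

random_expression <- function(classes = c("A", "B", "C"),
                              roles = c("r", "s"), depth = 2L) {
  if (depth <= 0L) return(ce_named(sample(classes, 1L)))
  op <- sample(c("named", "named", "not", "and", "or", "some", "only"), 1L)
  switch(op,
    named = ce_named(sample(classes, 1L)),
    not = ce_not(random_expression(classes, roles, depth - 1L)),
    and = ce_and(random_expression(classes, roles, depth - 1L),
                 random_expression(classes, roles, depth - 1L)),
    or = ce_or(random_expression(classes, roles, depth - 1L),
               random_expression(classes, roles, depth - 1L)),
    some = ce_some(sample(roles, 1L),
                   random_expression(classes, roles, depth - 1L)),
    only = ce_only(sample(roles, 1L),
                   random_expression(classes, roles, depth - 1L)))
}

tiny_ontology <- function() {
  o <- ontology()
  o <- add_role(o, role_declaration("r"))
  o <- add_axiom(o, ax_subclass(ce_named("A"), ce_named("B")), "t1")
  o <- add_axiom(o, ax_subclass(ce_named("B"), ce_named("C")), "t2")
  o
}

random_obo_document <- function(n_terms = 8L) {
  rels <- c("part_of", "regulates", "has_input")
  ids <- sprintf("T:%03d", seq_len(n_terms))
  terms <- lapply(seq_len(n_terms), function(i) {
    rel <- list()
    if (i > 1L && stats::runif(1) < 0.6)
      rel[[1L]] <- c(sample(rels, 1L), sample(ids[-i], 1L))
    xp <- list()
    if (i > 2L && stats::runif(1) < 0.4)
      xp <- list(c(NA_character_, sample(ids[seq_len(i - 1L)], 1L)),
                 c(sample(rels, 1L), sample(ids[-i], 1L)))
    obo_term(ids[i], name = paste("term", i), is_a = if (i > 1L &&
      stats::runif(1) < 0.5) sample(ids[seq_len(i - 1L)], 1L) else character(),
      relationship = rel, intersection_of = xp,
      is_obsolete = stats::runif(1) < 0.1)
  })
  obo_document(terms = terms)
}
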