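#' @title The minimal upper-level ontology and relation templates
#'
#' @description Four mutually disjoint foundational classes --
#'   \emph{Material object}, \emph{Process}, \emph{Quality} and
#'   \emph{Function} -- together with an axiomatized set of relations
#'   (part-of, inheres-in, has-participant, has-input/-output,
#'   has-central-participant, realized-by, derives-from, results-in and
#'   their inverses).  Domain ontology classes are aligned to these roots
#'   by identifier prefix (and, for GO, by namespace), which is what turns
#'   modelling errors into detectable logical contradictions.
#' @name upper_ontology
NULL

#' Upper-class identifiers
#' @return named character vector of the four upper class ids.
#' @export
upper_classes <- function() {
  c(material = "MaterialObject", process = "Process",
    quality = "Quality", func = "Function")
}

#' Build the upper-level ontology
#'
#' Declares the four pairwise-disjoint upper classes and the relation
#' box: part-of is transitive and reflexive with inverse has-part;
#' proper-part-of is a transitive sub-role of part-of; inheres-in is
#' functional (a quality inheres in at most one thing) with domain
#' Quality and unrestricted range; has-input, has-output and
#' has-central-participant are sub-roles of has-participant; realized-by
#' links functions to the processes realizing them.  Domain and range
#' restrictions are attached to the role declarations and compiled to
#' subclass axioms by the reasoner.
#'
#' @return a \code{dl_ontology}.
#' @export
build_upper_ontology <- function() {
  u <- upper_classes()
  MO <- ce_named(u[["material"]]); PR <- ce_named(u[["process"]])
  QU <- ce_named(u[["quality"]]); FN <- ce_named(u[["func"]])
  o <- ontology()
  o <- add_class(o, unname(u))
  o <- add_axiom(o, ax_disjoint(list(MO, PR, QU, FN)), "upper:disjoint")

  decl <- function(o, ...) add_role(o, role_declaration(...))
  o <- decl(o, "function_of", inverse = "has_function", domain = FN, range = MO)
  o <- decl(o, "has_function", inverse = "function_of", domain = MO, range = FN)
  # range of inheres_in is Thing: deliberately unrestricted, because
  # phenotype definitions apply qualities to material objects, processes
  # and functions alike
  o <- decl(o, "inheres_in", inverse = "has_quality", functional = TRUE,
            domain = QU, range = NULL)
  o <- decl(o, "has_quality", inverse = "inheres_in", domain = NULL, range = QU)
  o <- decl(o, "derives_from", domain = MO, range = MO)
  o <- decl(o, "has_participant", inverse = "participates_in",
            domain = PR, range = MO)
  o <- decl(o, "participates_in", inverse = "has_participant",
            domain = MO, range = PR)
  o <- decl(o, "has_input", inverse = "input_of", domain = PR, range = MO,
            super_roles = "has_participant")
  o <- decl(o, "input_of", inverse = "has_input", domain = MO, range = PR,
            super_roles = "participates_in")
  o <- decl(o, "has_output", inverse = "output_of", domain = PR, range = MO,
            super_roles = "has_participant")
  o <- decl(o, "output_of", inverse = "has_output", domain = MO, range = PR,
            super_roles = "participates_in")
  o <- decl(o, "has_central_participant", inverse = "central_participant_of",
            domain = PR, range = MO, super_roles = "has_participant")
  o <- decl(o, "central_participant_of", inverse = "has_central_participant",
            domain = MO, range = PR, super_roles = "participates_in")
  o <- decl(o, "part_of", inverse = "has_part", transitive = TRUE,
            reflexive = TRUE)
  o <- decl(o, "has_part", inverse = "part_of", transitive = TRUE,
            reflexive = TRUE)
  o <- decl(o, "proper_part_of", inverse = "has_proper_part",
            transitive = TRUE, super_roles = "part_of")
  o <- decl(o, "has_proper_part", inverse = "proper_part_of",
            transitive = TRUE, super_roles = "has_part")
  o <- decl(o, "realized_by", inverse = "realizes", domain = FN, range = PR)
  o <- decl(o, "realizes", inverse = "realized_by", domain = PR, range = FN)
  o <- decl(o, "results_in", domain = PR, range = PR)
  o
}

# ---------------------------------------------------------------------------
# Relation-expansion templates
# ---------------------------------------------------------------------------

#' Relation-expansion templates
#'
#' A template is a class-expression body with exactly one occurrence of
#' the placeholder class \code{?Y}.  A class-class relation statement
#' \code{C R D} is expanded to \code{C SubClassOf body[?Y := D]}.
#'
#' @param name relation identifier the template defines.
#' @param body either a \code{dl_ce} or a Manchester-style string
#'   containing \code{?Y} exactly once.
#' @return a \code{relation_template}.
#' @export
relation_template <- function(name, body) {
  if (is.character(body)) body <- parse_class_expression(body)
  stopifnot(inherits(body, "dl_ce"))
  n_placeholder <- count_placeholder(body)
  if (n_placeholder != 1L)
    stop("template body for '", name, "' must contain ?Y exactly once (found ",
         n_placeholder, ")")
  structure(list(name = name, body = body), class = "relation_template")
}

count_placeholder <- function(e) {
  switch(e$op,
    named = as.integer(e$id == "?Y"),
    top = ,
    bottom = 0L,
    not = count_placeholder(e$arg),
    and = ,
    or = sum(vapply(e$args, count_placeholder, 0L)),
    some = ,
    only = count_placeholder(e$filler)
  )
}

#' Expand a template with a filler
#' @param t a \code{relation_template}.
#' @param filler a class expression substituted for \code{?Y}.
#' @return the expanded class expression.
#' @export
expand_template <- function(t, filler) {
  stopifnot(inherits(t, "relation_template"), inherits(filler, "dl_ce"))
  ce_substitute(t$body, "?Y", filler)
}

#' Built-in template registry
#'
#' Templates for the relations whose semantics the method fixes:
#' plain existential expansion for the primitive upper-level relations,
#' and composite expansions for \code{inheres_in_part_of},
#' \code{has_function_realized_by} / \code{capable_of},
#' \code{inheres_in_has_central_participant}, \code{inheres_in_has_participant},
#' \code{realized_by_has_input} and \code{realized_by_has_output}.
#' Relations without a registered template default to
#' \code{R some ?Y} over a fresh primitive role \code{R}; composite
#' \code{results_in_*} relations are kept primitive but receive domain
#' \emph{Process} (see \code{\link{conversion_config}}).
#'
#' @return named list of \code{relation_template} objects.
#' @export
default_templates <- function() {
  tpl <- function(name, body) relation_template(name, body)
  plain <- c("part_of", "has_part", "proper_part_of", "inheres_in",
             "has_quality", "has_function", "function_of", "derives_from",
             "has_participant", "participates_in", "has_input", "has_output",
             "has_central_participant", "realized_by", "realizes")
  out <- lapply(plain, function(r) tpl(r, paste0(r, " some ?Y")))
  names(out) <- plain
  out$inheres_in_part_of <-
    tpl("inheres_in_part_of", "inheres_in some (part_of some ?Y)")
  out$has_function_realized_by <-
    tpl("has_function_realized_by", "has_function some (realized_by only ?Y)")
  out$capable_of <-
    tpl("capable_of", "has_function some (realized_by only ?Y)")
  out$inheres_in_has_central_participant <-
    tpl("inheres_in_has_central_participant",
        "inheres_in some (has_central_participant some ?Y)")
  out$inheres_in_has_participant <-
    tpl("inheres_in_has_participant",
        "inheres_in some (has_participant some ?Y)")
  out$realized_by_has_input <-
    tpl("realized_by_has_input", "realized_by only (has_input some ?Y)")
  out$realized_by_has_output <-
    tpl("realized_by_has_output", "realized_by only (has_output some ?Y)")
  out
}

#' Canonicalize a relation label
#'
#' Lower-cases and maps spaces and hyphens to underscores, so that the
#' spelling variants \code{has_part}, \code{has-part} and
#' \code{"has part"} all resolve to the same role identifier before the
#' synonym map is consulted.
#'
#' @param x character vector of relation labels or identifiers.
#' @return character vector of normalized identifiers.
#' @export
canonical_relation_id <- function(x) {
  gsub("[ -]+", "_", trimws(tolower(x)))
}

#' Default relation-synonym map
#'
#' Maps normalized spelling variants onto the canonical role identifiers
#' of the upper-level ontology.
#'
#' @return named character vector (variant -> canonical id).
#' @export
default_synonyms <- function() {
  c(partof = "part_of",
    haspart = "has_part",
    inheresin = "inheres_in",
    inheres_in_part_of = "inheres_in_part_of",
    quality_of = "inheres_in",
    has_agent_in = "has_agent",
    towards = "towards")
}

#' Conversion configuration
#'
#' Bundles everything the converter needs: the template registry, the
#' identifier-prefix to upper-class root map, the relation-synonym map,
#' the composite-role domain rules, and the analysis-mode flags.
#'
#' @param templates named list of \code{relation_template}s; defaults to
#'   \code{\link{default_templates}}.
#' @param root_map named character vector mapping an identifier prefix
#'   (the part before \code{":"}) to one of the four upper classes, or to
#'   \code{"namespace"} for GO-style routing by the term's namespace tag
#'   (\code{biological_process} to Process, \code{cellular_component} to
#'   Material object, \code{molecular_function} per \code{mf_mode}).
#' @param mf_mode \code{"function"} or \code{"process"}: which upper class
#'   the molecular-function namespace is aligned to.  Both readings are
#'   defensible, so analyses are typically run twice.
#' @param synonyms named character vector mapping normalized relation
#'   labels to canonical role identifiers.
#' @param strip_asserted_isa drop axioms that come from explicit
#'   \code{is_a} lines (definition-derived subsumptions survive), used to
#'   isolate contradictions caused by the formal definitions themselves.
#' @param add_quality_constraints add the axioms that qualities of
#'   processes inhere in processes and qualities of physical objects in
#'   material objects (requires \code{quality_roots}).
#' @param quality_roots named character vector with entries
#'   \code{process} and \code{physical}: the two quality root classes the
#'   constraints attach to.
#' @param functional_inheres_in declare inheres-in functional (default
#'   TRUE); exposed so the independent causes of an unsatisfiability can
#'   be switched off one at a time.
#' @param composite_domain_rules named character vector mapping a regular
#'   expression on relation identifiers to an upper class: any
#'   unregistered relation matching the pattern stays primitive but
#'   receives that domain.  The default gives every \code{results_in*}
#'   relation domain Process.
#' @param disambiguate character vector of relation identifiers to expand
#'   disjunctively using the registered \code{\link{disambiguation_rules}}.
#' @return a \code{conversion_config} object.
#' @export
conversion_config <- function(templates = default_templates(),
                              root_map = default_root_map(),
                              mf_mode = c("function", "process"),
                              synonyms = default_synonyms(),
                              strip_asserted_isa = FALSE,
                              add_quality_constraints = FALSE,
                              quality_roots = c(process = NA_character_,
                                                physical = NA_character_),
                              functional_inheres_in = TRUE,
                              composite_domain_rules =
                                c("^results_in" = "Process"),
                              disambiguate = character()) {
  mf_mode <- match.arg(mf_mode)
  u <- upper_classes()
  bad <- setdiff(setdiff(unname(root_map), "namespace"), unname(u))
  if (length(bad) > 0L)
    stop("root_map values must be upper classes or 'namespace': ",
         paste(bad, collapse = ", "))
  structure(list(templates = templates, root_map = root_map,
                 mf_mode = mf_mode, synonyms = synonyms,
                 strip_asserted_isa = isTRUE(strip_asserted_isa),
                 add_quality_constraints = isTRUE(add_quality_constraints),
                 quality_roots = quality_roots,
                 functional_inheres_in = isTRUE(functional_inheres_in),
                 composite_domain_rules = composite_domain_rules,
                 disambiguate = as.character(disambiguate)),
            class = "conversion_config")
}

#' Default identifier-prefix root map
#'
#' PATO classes are qualities; FMA, MA, CL, PRO, CHEBI and UBERON
#' classes are material objects; GO terms are routed by namespace.
#'
#' @return named character vector.
#' @export
default_root_map <- function() {
  c(PATO = "Quality", FMA = "MaterialObject", MA = "MaterialObject",
    CL = "MaterialObject", PR = "MaterialObject", CHEBI = "MaterialObject",
    UBERON = "MaterialObject", GO = "namespace")
}

#' Read a conversion configuration from a YAML file
#'
#' Recognized keys: \code{root_map} (prefix: upper class), \code{templates}
#' (relation: Manchester body with \code{?Y}), \code{synonyms}
#' (variant: canonical), \code{mf_mode}, \code{strip_asserted_isa},
#' \code{add_quality_constraints}, \code{quality_roots}
#' (\code{process}/\code{physical}), \code{functional_inheres_in},
#' \code{disambiguate} (list of relation ids).  Omitted keys fall back to
#' the built-in defaults; template entries override the built-ins
#' per-relation.
#'
#' @param path YAML file path.
#' @return a \code{conversion_config}.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  tpl <- default_templates()
  for (nm in names(y$templates))
    tpl[[nm]] <- relation_template(nm, y$templates[[nm]])
  root_map <- default_root_map()
  if (!is.null(y$root_map)) root_map <- unlist(y$root_map)
  syn <- default_synonyms()
  if (!is.null(y$synonyms)) {
    extra <- unlist(y$synonyms)
    syn[names(extra)] <- extra
  }
  qr <- c(process = NA_character_, physical = NA_character_)
  if (!is.null(y$quality_roots)) {
    qr[["process"]] <- y$quality_roots$process %||% NA_character_
    qr[["physical"]] <- y$quality_roots$physical %||% NA_character_
  }
  conversion_config(
    templates = tpl, root_map = root_map,
    mf_mode = y$mf_mode %||% "function",
    synonyms = syn,
    strip_asserted_isa = isTRUE(y$strip_asserted_isa),
    add_quality_constraints = isTRUE(y$add_quality_constraints),
    quality_roots = qr,
    functional_inheres_in = !isFALSE(y$functional_inheres_in),
    disambiguate = as.character(y$disambiguate %||% character()))
}

#' Write a conversion configuration to YAML
#' @param cfg a \code{conversion_config}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "conversion_config"))
  custom <- list()
  builtin <- default_templates()
  for (nm in names(cfg$templates)) {
    b <- cfg$templates[[nm]]$body$k
    if (is.null(builtin[[nm]]) || builtin[[nm]]$body$k != b)
      custom[[nm]] <- b
  }
  y <- list(root_map = as.list(cfg$root_map),
            mf_mode = cfg$mf_mode,
            strip_asserted_isa = cfg$strip_asserted_isa,
            add_quality_constraints = cfg$add_quality_constraints,
            functional_inheres_in = cfg$functional_inheres_in,
            synonyms = as.list(cfg$synonyms),
            disambiguate = as.list(cfg$disambiguate))
  if (length(custom) > 0L) y$templates <- custom
  if (!all(is.na(cfg$quality_roots)))
    y$quality_roots <- list(process = unname(cfg$quality_roots[["process"]]),
                            physical = unname(cfg$quality_roots[["physical"]]))
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
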