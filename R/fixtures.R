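#' @title Executable worked examples and planted-contradiction generator
#'
#' @description Small, self-contained OBO documents reproducing the
#'   classic contradiction patterns end to end -- a local disjointness
#'   clash (a spore defined as both a fungal and a prokaryotic cell), a
#'   global cross-ontology clash (leukocyte activation), a homonymy
#'   clash (the anatomical versus the process reading of "secretion"),
#'   a doubly-caused clash (liver inflammation), an improper relation
#'   use (host cell cytoplasm part), an expressive cross-ontology query
#'   (abdominal vasculature phenotypes), and a disambiguation scenario
#'   -- plus a seeded generator of random ontologies with planted,
#'   ground-truth contradictions for property testing.  Expected values
#'   in each bundle are fixed by construction, never by running the
#'   reasoner.
#' @name fixtures
NULL

fixture_names <- c("spore", "leukocyte_activation", "mucus_secretion",
                   "liver_inflammation", "host_cell_cytoplasm_part",
                   "vasculature_query", "hcp_disambiguation")

#' Build a worked-example fixture bundle
#'
#' @param name one of \code{"spore"}, \code{"leukocyte_activation"},
#'   \code{"mucus_secretion"}, \code{"liver_inflammation"},
#'   \code{"host_cell_cytoplasm_part"}, \code{"vasculature_query"},
#'   \code{"hcp_disambiguation"}.
#' @return a \code{fixture_bundle}: list with \code{name},
#'   \code{document}, \code{config}, an \code{expected} record
#'   (unsatisfiable classes, subsumptions, query answers, resolution
#'   statuses, as applicable) and fixture-specific variant documents or
#'   configs.
#' @export
worked_example <- function(name) {
  name <- match.arg(name, fixture_names)
  bundle <- switch(name,
    spore = fx_spore(),
    leukocyte_activation = fx_leukocyte(),
    mucus_secretion = fx_mucus(),
    liver_inflammation = fx_liver(),
    host_cell_cytoplasm_part = fx_host_cell(),
    vasculature_query = fx_vasculature(),
    hcp_disambiguation = fx_hcp())
  bundle$name <- name
  class(bundle) <- "fixture_bundle"
  bundle
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("<fixture bundle> ", x$name, "\n", sep = "")
  invisible(x)
}

fx_spore <- function() {
  doc <- obo_document(terms = list(
    obo_term("CL:EukaryoticCell", "eukaryotic cell",
             disjoint_from = "CL:ProkaryoticCell"),
    obo_term("CL:ProkaryoticCell", "prokaryotic cell"),
    obo_term("CL:FungalCell", "fungal cell", is_a = "CL:EukaryoticCell"),
    obo_term("CL:Spore", "spore",
             intersection_of = list("CL:FungalCell", "CL:ProkaryoticCell")),
    obo_term("GO:Sporulation", "sporulation",
             namespace = "biological_process"),
    obo_term("GO:SporulationResultingInFormationOfACellularSpore",
             "sporulation resulting in formation of a cellular spore",
             namespace = "biological_process",
             intersection_of = list(
               "GO:Sporulation",
               c("results_in_formation_of", "CL:Spore"))),
    obo_term("GO:SporeWallBiogenesis", "spore wall biogenesis",
             namespace = "biological_process",
             relationship = list(
               c("part_of",
                 "GO:SporulationResultingInFormationOfACellularSpore"))),
    obo_term("GO:SporeWallAssembly", "spore wall assembly",
             namespace = "biological_process",
             relationship = list(c("part_of", "GO:SporeWallBiogenesis")))))
  list(document = doc, config = conversion_config(),
       expected = list(unsatisfiable = c(
         "CL:Spore",
         "GO:SporeWallAssembly",
         "GO:SporeWallBiogenesis",
         "GO:SporulationResultingInFormationOfACellularSpore")))
}

fx_leukocyte <- function() {
  doc <- obo_document(terms = list(
    obo_term("GO:BiologicalProcess", "biological process",
             namespace = "biological_process"),
    obo_term("GO:CellularProcess", "cellular process",
             namespace = "biological_process", is_a = "GO:BiologicalProcess"),
    obo_term("GO:MulticellularOrganismalProcess",
             "multicellular organismal process",
             namespace = "biological_process", is_a = "GO:BiologicalProcess",
             disjoint_from = "GO:CellularProcess"),
    obo_term("GO:CellActivation", "cell activation",
             namespace = "biological_process", is_a = "GO:CellularProcess"),
    obo_term("GO:SystemProcess", "system process",
             namespace = "biological_process",
             is_a = "GO:MulticellularOrganismalProcess",
             intersection_of = list(
               "GO:BiologicalProcess",
               c("has_agent", "UBERON:AnatomicalSystem"))),
    obo_term("GO:ImmuneSystemProcess", "immune system process",
             namespace = "biological_process",
             intersection_of = list(
               "GO:BiologicalProcess",
               c("has_agent", "UBERON:ImmuneSystem"))),
    obo_term("GO:LeukocyteActivation", "leukocyte activation",
             namespace = "biological_process",
             is_a = "GO:ImmuneSystemProcess",
             intersection_of = list(
               "GO:CellActivation",
               c("has_input", "CL:Leukocyte"))),
    obo_term("UBERON:AnatomicalSystem", "anatomical system"),
    obo_term("UBERON:ImmuneSystem", "immune system",
             is_a = "UBERON:AnatomicalSystem"),
    obo_term("CL:Leukocyte", "leukocyte")),
    typedefs = list(
      obo_typedef("has_agent", "has agent",
                  domain = "Process", range = "MaterialObject")))
  list(document = doc, config = conversion_config(),
       expected = list(
         unsatisfiable = "GO:LeukocyteActivation",
         subsumptions = list(c(sup = "GO:SystemProcess",
                               sub = "GO:ImmuneSystemProcess"))))
}

fx_mucus <- function() {
  secretion_def <- function(genus) obo_term(
    "GO:MucusSecretion", "mucus secretion",
    namespace = "biological_process",
    intersection_of = list(genus, c("results_in_release_of", "CHEBI:Mucus")))
  base_terms <- list(
    obo_term("UBERON:Secretion", "secretion"),
    obo_term("GO:SecretionProcess", "secretion",
             namespace = "biological_process"),
    obo_term("CHEBI:Mucus", "mucus"))
  doc <- obo_document(terms = c(base_terms,
                                list(secretion_def("UBERON:Secretion"))))
  variant <- obo_document(terms = c(base_terms,
                                    list(secretion_def("GO:SecretionProcess"))))
  list(document = doc, variant_document = variant,
       config = conversion_config(),
       expected = list(unsatisfiable = "GO:MucusSecretion",
                       variant_unsatisfiable = character()))
}

fx_liver <- function() {
  doc <- obo_document(terms = list(
    obo_term("PATO:ProcessQuality", "process quality"),
    obo_term("PATO:PhysicalQuality", "physical quality"),
    obo_term("PATO:Functionality", "functionality",
             is_a = "PATO:PhysicalQuality"),
    obo_term("PATO:IncreasedRate", "increased rate",
             is_a = "PATO:ProcessQuality"),
    obo_term("MA:Liver", "liver"),
    obo_term("GO:InflammatoryResponse", "inflammatory response",
             namespace = "biological_process",
             relationship = list(c("has_participant", "MA:Liver"))),
    obo_term("MP:AbnormalLiverPhysiology", "abnormal liver physiology",
             intersection_of = list("PATO:Functionality",
                                    c("inheres_in", "MA:Liver"))),
    obo_term("MP:LiverInflammation", "liver inflammation",
             is_a = "MP:AbnormalLiverPhysiology",
             intersection_of = list("PATO:IncreasedRate",
                                    c("inheres_in",
                                      "GO:InflammatoryResponse")))))
  cfg <- conversion_config(
    add_quality_constraints = TRUE,
    quality_roots = c(process = "PATO:ProcessQuality",
                      physical = "PATO:PhysicalQuality"))
  list(document = doc, config = cfg,
       expected = list(
         unsatisfiable = "MP:LiverInflammation",
         # the clash has two independent causes; removing one alone
         # does not repair the class
         unsat_without_functionality = "MP:LiverInflammation",
         unsat_without_quality_constraints = "MP:LiverInflammation",
         unsat_without_both = character()))
}

fx_host_cell <- function() {
  doc <- obo_document(terms = list(
    obo_term("GO:HostCellPart", "host cell part",
             namespace = "cellular_component"),
    obo_term("GO:Cytoplasm", "cytoplasm",
             namespace = "cellular_component"),
    obo_term("GO:HostCellCytoplasmPart", "host cell cytoplasm part",
             namespace = "cellular_component",
             intersection_of = list("GO:HostCellPart",
                                    c("inheres_in", "GO:Cytoplasm")))))
  list(document = doc, config = conversion_config(),
       expected = list(unsatisfiable = "GO:HostCellCytoplasmPart"))
}

fx_vasculature <- function() {
  mk_terms <- function(kidney_vessel_is_a) list(
    obo_term("MA:AbdomenOrgan", "abdomen organ"),
    obo_term("MA:Liver", "liver", is_a = "MA:AbdomenOrgan"),
    obo_term("MA:Kidney", "kidney", is_a = "MA:AbdomenOrgan"),
    obo_term("MA:Heart", "heart"),
    obo_term("MA:VascularSystem", "vascular system"),
    obo_term("MA:BloodVessel", "blood vessel",
             relationship = list(c("part_of", "MA:VascularSystem"))),
    obo_term("MA:KidneyBloodVessel", "kidney blood vessel",
             is_a = kidney_vessel_is_a),
    obo_term("PATO:Abnormal", "abnormal"),
    obo_term("MP:LiverVascularCongestion", "liver vascular congestion",
             intersection_of = list(
               "PATO:Abnormal",
               c("inheres_in_part_of", "MA:Liver"),
               c("inheres_in", "MA:BloodVessel"))),
    obo_term("MP:AbnormalLiverVasculatureMorphology",
             "abnormal liver vasculature morphology",
             intersection_of = list(
               "PATO:Abnormal",
               c("inheres_in_part_of", "MA:Liver"),
               c("inheres_in", "MA:BloodVessel"))),
    obo_term("MP:KidneyVascularCongestion", "kidney vascular congestion",
             intersection_of = list(
               "PATO:Abnormal",
               c("inheres_in_part_of", "MA:Kidney"),
               c("inheres_in", "MA:KidneyBloodVessel"))),
    obo_term("MP:AbnormalHeartMorphology", "abnormal heart morphology",
             intersection_of = list(
               "PATO:Abnormal",
               c("inheres_in", "MA:Heart"))))
  cfg <- conversion_config()
  # without the inheres-in-part-of expansion the relation stays a fresh
  # primitive role and no cross-ontology inference is possible
  tpl_strict <- default_templates()
  tpl_strict$inheres_in_part_of <- NULL
  cfg_no_expansion <- conversion_config(templates = tpl_strict)
  list(document = obo_document(terms = mk_terms(character())),
       document_kidney = obo_document(terms = mk_terms("MA:BloodVessel")),
       config = cfg, config_no_expansion = cfg_no_expansion,
       query = paste("Quality and inheres_in some",
                     "((part_of some MA:AbdomenOrgan) and",
                     "(part_of some MA:VascularSystem))"),
       expected = list(
         query_answers = c("MP:AbnormalLiverVasculatureMorphology",
                           "MP:LiverVascularCongestion"),
         query_answers_kidney = c("MP:AbnormalLiverVasculatureMorphology",
                                  "MP:KidneyVascularCongestion",
                                  "MP:LiverVascularCongestion"),
         query_answers_no_expansion = character(),
         unsatisfiable = character()))
}

fx_hcp <- function() {
  doc <- obo_document(terms = list(
    obo_term("PATO:Abnormal", "abnormal"),
    obo_term("MA:Muscle", "muscle"),
    obo_term("MA:Eye", "eye"),
    obo_term("MA:Brain", "brain"),
    obo_term("MA:Heart", "heart"),
    obo_term("GO:HeartDevelopment", "heart development",
             namespace = "biological_process"),
    obo_term("CHEBI:Lactose", "lactose"),
    obo_term("MP:AbnormalMuscleContractility",
             "abnormal muscle contractility",
             intersection_of = list(
               "PATO:Abnormal",
               c("has_central_participant", "MA:Muscle"))),
    obo_term("MP:AbnormalEyeMovement", "abnormal eye movement",
             intersection_of = list(
               "PATO:Abnormal",
               c("has_central_participant", "MA:Eye"))),
    obo_term("MP:AbnormalBrainWavePattern", "abnormal brain wave pattern",
             intersection_of = list(
               "PATO:Abnormal",
               c("has_central_participant", "MA:Brain"))),
    obo_term("MP:HeartMixup", "heart mixup",
             intersection_of = list("MA:Heart", "GO:HeartDevelopment")),
    obo_term("GO:LactoseCatabolism", "lactose catabolism",
             namespace = "biological_process",
             relationship = list(c("has_input", "CHEBI:Lactose")))))
  misuse <- c("MP:AbnormalBrainWavePattern", "MP:AbnormalEyeMovement",
              "MP:AbnormalMuscleContractility")
  cfg_strict <- conversion_config()
  cfg_disamb <- conversion_config(
    disambiguate = c("has_central_participant", "has_input"))
  list(document = doc, config = cfg_strict, config_disambiguated = cfg_disamb,
       misuse_classes = misuse,
       expected = list(
         unsatisfiable = sort(c(misuse, "MP:HeartMixup")),
         unsatisfiable_disambiguated = "MP:HeartMixup",
         resolution = list(has_central_participant =
                             stats::setNames(rep("unintended", 3L), misuse),
                           has_input = c("GO:LactoseCatabolism" = "intended")),
         unsatisfiable_after_rewrite = "MP:HeartMixup"))
}

# ---------------------------------------------------------------------------
# Random ontologies with planted contradictions
# ---------------------------------------------------------------------------

#' Specify a planted-contradiction generator run
#'
#' @param seed integer RNG seed; identical seed and sizes reproduce the
#'   document exactly.
#' @param n_classes number of domain classes (spread over the four upper
#'   roots).
#' @param plants named integer vector with any of the entries
#'   \code{disjoint_intersection}, \code{domain_violation},
#'   \code{homonymy_merge}, \code{functional_merge_clash},
#'   \code{ambiguous_relation_use}: how many contradictions of each
#'   pattern to plant.
#' @param p_isa,p_partof,p_definition,p_inheres probabilities of the
#'   benign structure: an is-a parent within the class's root group, a
#'   benign part-of relationship, a benign cross-product definition, and
#'   (for quality classes) a benign inheres-in assertion.
#' @return a \code{plant_spec}.
#' @export
plant_spec <- function(seed, n_classes = 24L,
                       plants = c(disjoint_intersection = 1L,
                                  domain_violation = 1L,
                                  homonymy_merge = 1L,
                                  functional_merge_clash = 1L,
                                  ambiguous_relation_use = 1L),
                       p_isa = 0.7, p_partof = 0.3, p_definition = 0.2,
                       p_inheres = 0.3) {
  all_cat <- c(disjoint_intersection = 0L, domain_violation = 0L,
               homonymy_merge = 0L, functional_merge_clash = 0L,
               ambiguous_relation_use = 0L)
  bad <- setdiff(names(plants), names(all_cat))
  if (length(bad) > 0L) stop("unknown plant categories: ",
                             paste(bad, collapse = ", "))
  all_cat[names(plants)] <- as.integer(plants)
  structure(list(seed = as.integer(seed), n_classes = as.integer(n_classes),
                 plants = all_cat, p_isa = p_isa, p_partof = p_partof,
                 p_definition = p_definition, p_inheres = p_inheres),
            class = "plant_spec")
}

planted_root_map <- function() {
  c(MOX = "MaterialObject", PRX = "Process", QUX = "Quality",
    FNX = "Function")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a random ontology with planted contradictions
#'
#' Builds a random is-a forest over classes pre-assigned to the four
#' upper roots (prefixes \code{MOX}, \code{PRX}, \code{QUX},
#' \code{FNX}), adds benign part-of / inheres-in structure and benign
#' cross-product definitions, then plants the requested contradictions:
#' \describe{
#'   \item{disjoint_intersection}{a class defined as the intersection of
#'     classes under two disjoint roots (local contradiction);}
#'   \item{domain_violation}{a material-object class asserted to
#'     \code{has_participant} something (domain Process);}
#'   \item{homonymy_merge}{a process class whose definition's genus
#'     lives under Material object while a \code{results_in_*} relation
#'     forces Process;}
#'   \item{functional_merge_clash}{a quality inhering in both a material
#'     object and a process, merged by functional inheres-in;}
#'   \item{ambiguous_relation_use}{a quality class using
#'     \code{has_central_participant} toward a material object
#'     (resolvable by disambiguation).}
#' }
#' The expected unsatisfiable set is the planted classes plus their
#' dependency closure (classes reaching a planted class through is-a,
#' relationship, or definition references), computed by a graph walk on
#' the document -- independent of the reasoner.
#'
#' @param spec a \code{\link{plant_spec}}.
#' @return a \code{fixture_bundle} with \code{document}, \code{config},
#'   \code{expected} (fields \code{unsatisfiable}, \code{planted},
#'   \code{unsatisfiable_disambiguated}) and the per-category victim
#'   ids.
#' @export
generate_planted <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  n_plants <- sum(spec$plants)
  if (n_plants > spec$n_classes %/% 2L)
    stop("infeasible spec: ", n_plants, " plants for ", spec$n_classes,
         " classes")
  with_seed(spec$seed, {
    prefixes <- names(planted_root_map())
    groups <- rep_len(prefixes, spec$n_classes)
    ids <- sprintf("%s:%04d", groups, seq_len(spec$n_classes))
    by_group <- split(ids, groups)

    # choose victims per category, respecting the group each pattern needs
    pool <- ids
    pick <- function(k, from) {
      from <- intersect(from, pool)
      if (length(from) < k)
        stop("infeasible spec: not enough classes in the required root group")
      v <- if (k > 0L) sample(from, k) else character()
      pool <<- setdiff(pool, v)
      v
    }
    victims <- list(
      disjoint_intersection =
        pick(spec$plants[["disjoint_intersection"]], ids),
      domain_violation =
        pick(spec$plants[["domain_violation"]], by_group$MOX),
      homonymy_merge =
        pick(spec$plants[["homonymy_merge"]], by_group$PRX),
      functional_merge_clash =
        pick(spec$plants[["functional_merge_clash"]], by_group$QUX),
      ambiguous_relation_use =
        pick(spec$plants[["ambiguous_relation_use"]], by_group$QUX))
    all_victims <- unlist(victims, use.names = FALSE)

    earlier_same_group <- function(id) {
      g <- by_group[[term_prefix(id)]]
      g[seq_len(match(id, g) - 1L)]
    }
    rand1 <- function(xs) if (length(xs) == 0L) NULL else
      xs[[sample.int(length(xs), 1L)]]

    terms <- list()
    for (id in ids) {
      isa <- character()
      relationship <- list()
      intersection <- list()
      prior <- earlier_same_group(id)
      if (length(prior) > 0L && stats::runif(1) < spec$p_isa)
        isa <- rand1(prior)
      if (!(id %in% all_victims)) {
        others <- setdiff(by_group[[term_prefix(id)]], id)
        if (length(prior) > 0L && length(others) > 0L &&
            stats::runif(1) < spec$p_definition) {
          # defined classes are pure cross-products with no other
          # assertions: any extra necessary condition (asserted parent
          # or relationship) would let the equivalence's sufficient
          # direction pull sibling classes under it (e.g. via reflexive
          # part-of), creating contradictions the bookkeeping graph
          # walk cannot see
          intersection <- list(rand1(prior), c("part_of", rand1(others)))
          isa <- character()
        } else {
          if (length(others) > 0L && stats::runif(1) < spec$p_partof)
            relationship[[length(relationship) + 1L]] <-
              c("part_of", rand1(others))
          if (term_prefix(id) == "QUX" && length(by_group$MOX) > 0L &&
              stats::runif(1) < spec$p_inheres)
            relationship[[length(relationship) + 1L]] <-
              c("inheres_in", rand1(by_group$MOX))
        }
      }
      terms[[id]] <- obo_term(id, name = tolower(id), is_a = isa,
                              relationship = relationship,
                              intersection_of = intersection)
    }

    # plant the contradictions
    cross_groups <- function(exclude) {
      gs <- sample(prefixes, 2L)
      c(rand1(setdiff(by_group[[gs[1L]]], exclude)),
        rand1(setdiff(by_group[[gs[2L]]], exclude)))
    }
    for (v in victims$disjoint_intersection) {
      ab <- cross_groups(v)
      terms[[v]]$intersection_of <- list(c(NA_character_, ab[1L]),
                                         c(NA_character_, ab[2L]))
    }
    for (v in victims$domain_violation) {
      terms[[v]]$relationship <- c(terms[[v]]$relationship,
                                   list(c("has_participant",
                                          rand1(by_group$MOX))))
    }
    for (v in victims$homonymy_merge) {
      terms[[v]]$intersection_of <- list(
        c(NA_character_, rand1(by_group$MOX)),
        c("results_in_release_of", rand1(by_group$MOX)))
    }
    for (v in victims$functional_merge_clash) {
      terms[[v]]$relationship <- c(terms[[v]]$relationship, list(
        c("inheres_in", rand1(by_group$MOX)),
        c("inheres_in", rand1(by_group$PRX))))
    }
    for (v in victims$ambiguous_relation_use) {
      prior <- earlier_same_group(v)
      genus <- if (length(prior) > 0L) rand1(prior) else rand1(
        setdiff(by_group$QUX, v))
      terms[[v]]$intersection_of <- list(
        c(NA_character_, genus),
        c("has_central_participant", rand1(by_group$MOX)))
    }

    doc <- obo_document(terms = terms)
    cfg <- conversion_config(root_map = c(default_root_map(),
                                          planted_root_map()))

    closure <- function(seeds) {
      unsat <- seeds
      repeat {
        added <- FALSE
        for (f in doc$terms) {
          if (f$id %in% unsat) next
          refs <- c(f$is_a,
                    vapply(f$relationship, `[[`, "", 2L),
                    vapply(f$intersection_of, `[[`, "", 2L),
                    unlist(lapply(f$intersection_of, function(e)
                      if (is.na(e[1L])) e[2L] else NULL)))
          if (any(refs %in% unsat)) {
            unsat <- c(unsat, f$id)
            added <- TRUE
          }
        }
        if (!added) break
      }
      sort(unsat)
    }
    expected_unsat <- closure(all_victims)
    expected_disamb <- closure(setdiff(all_victims,
                                       victims$ambiguous_relation_use))
    structure(list(name = "planted", document = doc, config = cfg,
                   victims = victims,
                   expected = list(
                     planted = sort(all_victims),
                     unsatisfiable = expected_unsat,
                     unsatisfiable_disambiguated = expected_disamb)),
              class = "fixture_bundle")
  })
}

#' Generate a random small ontology in the ALC+transitive fragment
#'
#' Used to cross-check the tableau engine against the exhaustive
#' finite-model search: random concept inclusions over a few named
#' classes and one or two roles (each transitive with probability one
#' half), with right-hand sides of expression depth at most two.
#' Left-hand sides follow the shapes the OBO conversion pipeline
#' actually produces -- a named class, an intersection containing a
#' named class, or occasionally a single restriction (which exercises
#' the internalized-GCI path).  The fragment deliberately excludes
#' inverse and functional roles, whose interplay is covered by the
#' worked-example fixtures instead.
#'
#' @param seed integer seed.
#' @param n_classes,n_roles,n_axioms signature and axiom-count caps
#'   (the actual counts are sampled up to these).
#' @return list with \code{ontology} (a \code{dl_ontology}) and
#'   \code{probe} (a random class expression to test alongside the named
#'   classes).
#' @export
random_alc_ontology <- function(seed, n_classes = 5L, n_roles = 2L,
                                n_axioms = 8L) {
  with_seed(seed, {
    ncl <- sample.int(n_classes, 1L)
    nrl <- sample.int(n_roles, 1L)
    nax <- sample.int(n_axioms, 1L)
    classes <- paste0("C", seq_len(ncl))
    roles <- paste0("r", seq_len(nrl))
    trans <- stats::runif(nrl) < 0.5
    rand_expr <- function(depth) {
      if (depth <= 0L) return(ce_named(sample(classes, 1L)))
      op <- sample(c("named", "named", "not", "and", "or", "some", "only"),
                   1L)
      switch(op,
        named = ce_named(sample(classes, 1L)),
        not = ce_not(rand_expr(depth - 1L)),
        and = ce_and(rand_expr(depth - 1L), rand_expr(depth - 1L)),
        or = ce_or(rand_expr(depth - 1L), rand_expr(depth - 1L)),
        some = ce_some(sample(roles, 1L), rand_expr(depth - 1L)),
        only = ce_only(sample(roles, 1L), rand_expr(depth - 1L)))
    }
    restriction_lhs_used <- FALSE
    rand_lhs <- function() {
      u <- stats::runif(1)
      if (u >= 0.8 && !restriction_lhs_used) {
        # at most one restriction-shaped left-hand side per ontology:
        # several of them compound into needle-in-a-haystack search
        # spaces that say nothing more about correctness
        restriction_lhs_used <<- TRUE
        role <- sample(roles, 1L)
        filler <- ce_named(sample(classes, 1L))
        return(if (u < 0.9) ce_some(role, filler) else ce_only(role, filler))
      }
      if (u < 0.55) ce_named(sample(classes, 1L))
      else ce_and(ce_named(sample(classes, 1L)), rand_expr(1L))
    }
    o <- ontology()
    o <- add_class(o, classes)
    for (i in seq_len(nrl))
      o <- add_role(o, role_declaration(roles[i], transitive = trans[i]))
    for (i in seq_len(nax))
      o <- add_axiom(o, ax_subclass(rand_lhs(), rand_expr(2L)),
                     paste0("random:", i))
    list(ontology = o, probe = rand_expr(2L))
  })
}

#' Write a fixture bundle to disk
#'
#' Emits the OBO document(s), the conversion configuration (YAML) and
#' the expected record (JSON), so the complete command-line path
#' (parse, convert, check) can be exercised on genuine files.
#'
#' @param bundle a \code{fixture_bundle} (from
#'   \code{\link{worked_example}} or \code{\link{generate_planted}}).
#' @param dir output directory (created if needed).
#' @return invisibly, the named character vector of written paths.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  obo_path <- file.path(dir, paste0(bundle$name, ".obo"))
  write_obo(bundle$document, obo_path)
  paths["obo"] <- obo_path
  for (extra in grep("^(variant_document|document_)", names(bundle),
                     value = TRUE)) {
    p <- file.path(dir, paste0(bundle$name, "_", sub("^document_", "",
                                                     extra), ".obo"))
    write_obo(bundle[[extra]], p)
    paths[extra] <- p
  }
  cfg_path <- file.path(dir, paste0(bundle$name, "_config.yaml"))
  write_config(bundle$config, cfg_path)
  paths["config"] <- cfg_path
  exp_path <- file.path(dir, paste0(bundle$name, "_expected.json"))
  jsonlite::write_json(bundle$expected, exp_path, auto_unbox = TRUE,
                       pretty = TRUE)
  paths["expected"] <- exp_path
  invisible(paths)
}
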