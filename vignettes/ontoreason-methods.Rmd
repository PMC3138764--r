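---
title: "Making biomedical ontologies reasoning-safe: the methods behind ontoreason"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Making biomedical ontologies reasoning-safe: the methods behind ontoreason}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoreason)
```

## The model

`ontoreason` treats an OBO Flatfile ontology as a description-logic
knowledge base. The logic implemented is ALC extended with role
hierarchies, inverse roles, transitive roles, functional roles and role
domain/range restrictions — exactly the constructs the formalization
pipeline emits, and nothing more (no nominals, no datatypes, no
cardinalities beyond functionality). Class expressions are built from
named classes, `Thing`, `Nothing`, `not`, `and`, `or`, and the
restrictions `R some C` and `R only C`, written in a Manchester-like
concrete syntax.

Three modelling commitments do the real work.

**Relations between classes are one-argument templates.** OBO
`relationship:` lines and relational `intersection_of:` entries relate
*classes*, but the underlying semantics relates *instances*. Each
relation is therefore a template with a single placeholder `?Y` that
unfolds into a class description: `part_of` unfolds to
`part_of some ?Y`, the phenotype relation `inheres_in_part_of` to
`inheres_in some (part_of some ?Y)`, `capable_of` to
`has_function some (realized_by only ?Y)`. A statement `C R D` becomes
`C SubClassOf template(R)[?Y := D]`; a non-empty `intersection_of`
becomes an equivalence (cross-product definitions are definitions:
necessary *and* sufficient), while `relationship:` lines stay
necessary-only subclass axioms. Because templates produce class
*descriptions* rather than axioms, they compose under intersection and
union — which is what makes both cross-product definitions and the
disjunctive disambiguation machinery possible.

**A minimal upper level.** Four pairwise disjoint classes — *Material
object*, *Process*, *Quality*, *Function* — anchor every domain class,
by identifier prefix (PATO under Quality; FMA, MA, CL, PR, CHEBI and
UBERON under Material object) or, for GO, by namespace. The
molecular-function branch is genuinely ambiguous between *Function* and
*Process*, so the configuration exposes `mf_mode` and analyses are run
twice. The relation box carries the semantics that turns modelling
errors into logical clashes: `inheres_in` is functional (a quality
inheres in at most one thing) with domain *Quality* and deliberately
unrestricted range, because phenotype definitions apply qualities to
material objects, processes and functions alike; `has_participant` and
its sub-relations have domain *Process*; composite `results_in_*`
relations are not expanded (no defensible process decomposition exists
for all of them) but stay primitive with domain *Process* — which is
precisely what exposes homonymy errors like an anatomical *Secretion*
used where a process was meant.

**Optional domain constraints.** PATO distinguishes qualities of
processes from qualities of physical objects. With
`add_quality_constraints`, the two roots receive
`inheres_in only Process` and `inheres_in only MaterialObject`
respectively. The liver-inflammation fixture shows why this is kept
toggleable: that class is unsatisfiable for two independent reasons
(functional `inheres_in` merging a liver with an inflammatory response,
and the PATO constraints), and only disabling both repairs it —
single-cause repairs are diagnosable by toggling
`functional_inheres_in` and `add_quality_constraints` separately.

## The reasoner

Satisfiability is decided by a tableau procedure over labelled
completion graphs: nodes carry sets of NNF expressions, edges carry
role sets. The rules are standard — conjunction decomposition,
disjunction branching, existential successor creation, universal
propagation along implied super-roles and through inverses, the
transitivity rule (`only` restrictions re-propagate along transitive
sub-roles), functional-role successor merging (oldest node wins, edges
rewired), and a self-loop treatment of reflexive roles (every node is
its own neighbour for `part_of`). Subsumption, classification, query
answering and unsatisfiable-class enumeration all reduce to
satisfiability tests; justifications come from deletion-based
shrinking, which yields one subset-minimal axiom set per contradiction
(not all of them).

Choices a maintainer should know about:

* **Axiom internalization is lazy.** Axioms whose left-hand side is a
  named class (or an intersection containing one) are *absorbed*: the
  right-hand side fires only when the trigger class enters a node
  label. Residual general inclusions with complex left-hand sides are
  internalized as disjunctions added to every node. Role domains and
  ranges are deterministic edge rules. This is semantically equivalent
  to full internalization but removes almost all useless branching;
  with full internalization the deeper worked examples took seconds
  instead of milliseconds.
* **Branching.** Disjunctions are explored with chronological
  backtracking plus semantic branching (after a disjunct fails, its
  negation is asserted for the remaining alternatives) in a
  deterministic least-commitment order: literal disjuncts before
  universal restrictions before conjunctions before existentials.
  There is no dependency-directed backjumping; at the problem sizes
  this package targets it has not been needed.
* **Blocking.** With inverse or functional roles in play, pairwise
  (equality) ancestor blocking is used — subset blocking is unsound
  there. When the role box has neither (the ALC+transitive fragment
  used for the randomized cross-checks), the engine switches to subset
  anywhere blocking, which collapses completion trees much earlier.
* **Resource caps.** Node and branch caps (defaults `1e5`/`1e5`) make
  non-termination impossible in practice; exhausting a cap returns
  `NA` ("undecided"), which every downstream report carries explicitly
  — never a silent answer. The branch default is set so that the
  hardest randomly generated instances we observed (three interacting
  restriction-shaped axioms) still decide; they take a few seconds.

The engine is validated two ways: the worked-example fixtures pin its
behaviour on the inverse+functional interactions, and on 200 seeded
random ontologies in the ALC+transitive fragment every verdict is
compared against an independent decision procedure —
`model_check_satisfiable`, an exhaustive search for finite models of
domain size 1–4 that grounds the ontology to propositional clauses
(full Tseitin encoding) and decides them with a small DPLL (unit
propagation, failed-literal probing, chronological search). The two
implementations share nothing beyond the axiom-compilation helpers, so
agreement is meaningful. The oracle fragment excludes inverse and
functional roles, whose finite-model sizes are harder to bound; those
constructs are covered by the fixtures instead.

## Disambiguation and repair

A relation used in two formally disjoint ways — `has_central_participant`
asserted of qualities instead of processes,
`has_input`/`has_output` applied to functions as well as processes —
is given one template per meaning, joined disjunctively. For a
well-rooted class one disjunct always clashes, so per-use
satisfiability testing with each alternative substituted alone resolves
the use: exactly one satisfiable alternative gives `intended` or
`unintended`; both satisfiable gives `ambiguous` (reported, never
auto-resolved — an under-constrained class genuinely supports both
readings); none gives `neither`. Classes with several ambiguous uses
are tested one use at a time, with the other uses keeping their weaker
disjunctive expansion; this localizes each test and is equivalent to
asking whether some assignment of the other uses keeps the class
satisfiable.

One design point deserves emphasis. The function-reading alternatives
for `has_input`/`has_output` are
`Function and (realized_by only (has_input some ?Y))`, not the bare
universal restriction: a bare `only` is vacuously satisfiable for a
process class with no `realized_by` successors, which would leave every
intended use `ambiguous` instead of `intended`. The explicit `Function`
conjunct makes the two meanings formally disjoint, which is the
property the whole resolution mechanism rests on. The composite
relations introduced on rewriting (`realized_by_has_input`, ...) keep
the plain universal-restriction template: after rewriting, the class's
upper-level root already carries the disambiguated information. A
related subtlety is the `only` in `capable_of` /
`has_function_realized_by`: a function with no realization satisfies it
vacuously; the templates are kept as conventionally printed, and the
consequence is visible in resolution reports rather than papered over.

Resolved `unintended` uses are rewritten in the OBO source
(`rewrite_resolved`), replacing the relation identifier in the
offending line with the composite name; re-converting strictly then
removes exactly the ambiguity-caused contradictions while clashes with
other causes survive — the fixtures exercise this multiple-causes
behaviour explicitly.

## The synthetic-data generator

`generate_planted` builds random OBO documents over four prefix groups
pre-assigned to the upper roots: an is-a forest within each group,
benign `part_of` structure, benign single `inheres_in` assertions for
qualities, and benign cross-product definitions, plus planted
contradictions of five patterns (disjoint-root intersections, domain
violations, homonymy-style genus errors, functional-merge clashes, and
ambiguous `has_central_participant` uses). The expected unsatisfiable
set is the planted classes plus every class reaching one through is-a,
relationship or definition references — a graph walk on the document,
computed without the reasoner, so reasoner and bookkeeping are
independent witnesses.

Two generator invariants keep that bookkeeping *exact* rather than
merely sound. Benign defined classes are pure cross-products with no
other assertions: an extra asserted parent or relationship would let
the equivalence's sufficient direction pull sibling classes under it
(reflexive `part_of` makes `A and part_of some A` collapse to `A`),
creating contradictions no local graph walk can see. And victims carry
no benign tags beyond their is-a parent. Defaults (24 classes, one
plant per pattern, is-a probability 0.7, part-of 0.3, definition 0.2,
inheres-in 0.3) give documents in which roughly a quarter of classes
end up contradictory — dense enough to exercise dependency closure,
sparse enough that satisfiable structure dominates.

What the generator does *not* emulate: real XP definitions' vocabulary
scale (tens of thousands of classes), dangling cross-references into
unloaded ontologies, obsolete-term churn, multi-genus definitions, and
relation typos. Passing the planted-recovery sweep therefore shows the
detection machinery is correct on the patterns, not that real GO/MP/HPO
releases would yield any particular contradiction count — those depend
on the release snapshot and are out of scope here.

## Numerical and procedural choices

* Expressions are canonicalized at construction (flattening,
  deduplication, sorted arguments), so structural equality is key
  equality and all reports are deterministic; conversion of identical
  inputs is byte-identical.
* `intersection_of` with a single entry violates the OBO spec but
  occurs in the wild; it is accepted with a recorded warning.
* Obsolete terms are parsed and retained but excluded from conversion
  and counting; dangling references are reported, never dropped, and
  the referenced class is declared on the fly so reasoning proceeds.
* Relation labels are canonicalized (case, hyphens, spaces) and then
  passed through a synonym map, so `has_part`, `has-part` and
  `has part` are one role.
* Justification shrinking walks axioms in document order, giving a
  deterministic (first-found) minimal set.
* The problem sizes used by the test suite and the acceptance script —
  fixtures of 3–16 terms, 200 random ontologies of at most 5 classes,
  2 roles and 8 axioms checked against domain sizes up to 4, 100
  planted documents of 24 classes — were chosen as the scale at which
  the finite-model oracle is exhaustive and every property can be
  checked exactly; the toolkit itself has no hard-coded size limits
  beyond the reasoner's resource caps.

## Known limitations

* The reasoner is complete for the implemented fragment but engineered
  for curation-scale inputs (hundreds of classes), not for classifying
  a full GO release; the OWL functional-syntax export
  (`write_owl_functional`) exists to hand that job to an external
  reasoner.
* Reflexive roles are handled by a self-loop rule in neighbour
  computation; reflexivity interacting with number restrictions is out
  of fragment.
* `union_of` and OBO 1.4 constructs are parsed as opaque tags and
  reported unsupported rather than converted.
* One justification is computed per contradiction, not all; diagnoses
  with several independent causes (the liver-inflammation pattern)
  surface through configuration toggles instead.
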