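# ontoreason

Description-logic reasoning over OBO Flatfile ontologies: relation
expansion, upper-level alignment, contradiction detection and repair.

## The problem

Biomedical ontologies — the Gene Ontology (GO), the Mammalian Phenotype
Ontology (MP), the Human Phenotype Ontology (HPO), anatomy ontologies
like MA and UBERON, the PATO quality ontology — increasingly carry
*cross-product* (XP) logical definitions: a class is defined as the
intersection of a genus and relational differentia drawn from other
ontologies (`intersection_of:` tags in the OBO Flatfile Format). These
definitions only pay off if their semantics is explicit enough for an
automated reasoner: then contradictory definitions surface as
*unsatisfiable classes* (classes that can have no instances in any
model), and queries can cut across ontology boundaries ("all phenotypes
affecting the vasculature of abdominal organs") instead of being limited
to each ontology's asserted hierarchy.

`ontoreason` is a toolkit for ontology engineers and curators that makes
this workflow self-contained in R:

1. **Formalization.** Class–class relation statements `C R D` are
   treated as single-argument templates: `R` expands to a class
   expression with one placeholder, so `Nucleus part_of Cell` becomes
   `Nucleus SubClassOf (part_of some Cell)`, and composite relations
   unfold, e.g. `inheres_in_part_of` to
   `inheres_in some (part_of some ?Y)`. `intersection_of` definitions
   become equivalence axioms, `disjoint_from` becomes disjointness.
2. **Upper-level alignment.** Four mutually disjoint foundational
   classes — *Material object*, *Process*, *Quality*, *Function* — and
   an axiomatized relation box (`part_of` transitive and reflexive with
   inverse `has_part`; `inheres_in` functional — a quality inheres in at
   most one thing — with domain *Quality* and unrestricted range;
   `has_input`/`has_output`/`has_central_participant` below
   `has_participant` with domain *Process*; `realized_by` linking
   functions to processes; `results_in*` composites kept primitive with
   domain *Process*). Classes are routed to roots by identifier prefix
   (PATO to Quality; FMA/MA/CL/PR/CHEBI/UBERON to Material object) and,
   for GO, by namespace, with the molecular-function branch alignable to
   either *Function* or *Process* (both analyses are supported).
3. **Reasoning.** A built-in tableau engine for ALC plus role
   hierarchies, inverse, transitive and functional roles decides
   satisfiability, enumerates unsatisfiable classes, classifies,
   answers Manchester-style class-expression queries, and shrinks a
   minimal justification for each contradiction.
4. **Repair.** Relations used with two formally disjoint meanings are
   expanded *disjunctively* over both readings; since one disjunct
   clashes for any given class, reasoning resolves each use to its
   intended or unintended meaning, and resolved uses are rewritten in
   the source document with new composite relations
   (`inheres_in_has_central_participant`, `realized_by_has_input`, ...).

Everything is testable without downloads: worked-example fixtures
reproduce the classic contradiction patterns (local disjointness
clashes, global cross-ontology clashes, homonymy, improper relation
use), and a seeded generator plants contradictions with known ground
truth.

## Worked example

The shipped spore fixture reproduces a real (since fixed) local
contradiction in the Cell type Ontology: a spore defined as the
intersection of *Fungal cell* and *Prokaryotic cell*, while fungal cells
are eukaryotic and eukaryotic and prokaryotic cells are disjoint.

```r
library(ontoreason)

obo  <- system.file("extdata", "spore.obo", package = "ontoreason")
onto <- convert_obo(read_obo(obo), conversion_config())
onto
#> <ontology> 12 classes, 21 roles, 15 axioms

unsatisfiable_classes(onto)
#> [1] "CL:Spore"
#> [2] "GO:SporeWallAssembly"
#> [3] "GO:SporeWallBiogenesis"
#> [4] "GO:SporulationResultingInFormationOfACellularSpore"
```

Four classes are contradictory: the spore itself, and the three process
classes that depend on it existentially (sporulation resulting in a
spore, and the part-of chain spore wall biogenesis / assembly) — one bad
definition poisons everything built on it. A minimal justification names
the axioms at fault:

```r
justify(onto, "CL:Spore")$axioms
#> DisjointClasses(CL:EukaryoticCell, CL:ProkaryoticCell)
#> CL:FungalCell SubClassOf CL:EukaryoticCell
#> CL:Spore EquivalentTo (CL:FungalCell and CL:ProkaryoticCell)
```

Expressive cross-ontology queries work because composite relations are
expanded into primitives. In the vasculature fixture, liver phenotypes
are defined with `inheres_in_part_of` against the mouse anatomy; asking
for qualities of things that are part of an abdominal organ and part of
the vascular system retrieves them through the anatomy ontology's
part-of structure:

```r
b <- worked_example("vasculature_query")
o <- convert_obo(b$document, b$config)
query_subclasses(o, b$query)
#> [1] "MP:AbnormalLiverVasculatureMorphology"
#> [2] "MP:LiverVascularCongestion"
```

Without the `inheres_in_part_of` expansion the same query returns
nothing, and adding the missing `KidneyBloodVessel SubClassOf
BloodVessel` assertion makes the kidney phenotype retrievable as well.

A command-line interface wraps the same pipeline
(`exec/ontoreason`): `convert`, `check` (exit code 1 when
contradictions are found, 3 when any test was undecided), `query`,
`disambiguate`, `stats` and `fixture` subcommands.

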