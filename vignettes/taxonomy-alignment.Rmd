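---
title: "Aligning taxonomies with RCC-5 articulations: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning taxonomies with RCC-5 articulations: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxalign)
```

## The problem

Two classifications (or phylogenies) of the same organismal group rarely
use names consistently: a genus name kept across revisions may gain or
lose species, and a renamed clade may keep exactly the same
circumscription.  The *taxonomic concept* approach individuates every
name by its source ("name sec. author") and asks an expert to relate
concepts from two treatments with **RCC-5 articulations**: congruence
(`==`), proper inclusion (`>`), inverse proper inclusion (`<`), overlap
(`><`), and exclusion (`|`), possibly as a disjunction when the expert
is unsure.  Disjunctions of the five base relations form a lattice of
32 possible articulations, from the empty set to the maximally
ambiguous five-member set.

`taxalign` takes two concept hierarchies, a set of articulations, and
three taxonomic constraints, and answers: is this input logically
consistent?  If so, which complete *alignments* (possible worlds) does
it admit, which relation is entailed for *every* cross-taxonomy concept
pair (the maximally informative relations, MIR), which articulations
were redundant, and what does the merged taxonomy look like?  If not,
which minimal sets of articulations could be withdrawn?

## The semantic model

A concept's meaning is its extension (a set of instances).  The package
reasons over extensions symbolically through **Euler regions**: a region
is a set of concepts whose extensions jointly contain some instances.
Three constraints shape the admissible regions:

* **non-emptiness** — every concept has at least one instance;
* **sibling disjointness** — children of one parent within a taxonomy
  exclude each other;
* **coverage** — a parent is exactly the union of its children; it can
  be relaxed per parent with the `nc` flag, allowing the parent to
  extend beyond its listed children (used for genera whose full species
  lists a source does not print).

Under the default constraints, a region's membership restricted to one
taxonomy is a root-to-terminal chain (terminal = leaf, or `nc` parent),
so the candidate regions are pairs of chains — at most
(paths₁ + 1) × (paths₂ + 1) − 1 of them, not 2^(number of concepts).
Edges carry subset (not strict subset) semantics: a monotypic covered
parent is extensionally *congruent* to its single child, which is what
lets a 1936 monotypic genus sit inside a congruence cluster with its
only species.

A **possible world** is a choice of which candidate regions are
occupied such that every concept is non-empty and every articulation's
zone pattern (unique-to-left / shared / unique-to-right) matches one of
its permitted base relations.  Two occupancy choices that induce the
same base relation on every concept pair are the *same* world: world
identity is the induced relation assignment.  This projection
reproduces the published counts for the 1936/1954 use-case alignment
(1, 8, and 17 worlds as the input is progressively underspecified),
which are stated in terms of articulation outcomes, not region sets.

```{r}
length(enumerate_worlds(perelleschus(1, "underspec_L1")))
length(enumerate_worlds(perelleschus(1, "underspec_L2")))
```

## Solver and independent oracle

`enumerate_worlds()` searches region occupancy depth-first with two
prunes: an articulation prunes a branch when no permitted zone triple
remains realizable, and a concept prunes when all its regions are
decided empty.  Worlds are deduplicated by their relation-assignment
key and returned in a deterministic lexicographic order, so identical
inputs always give byte-identical outputs without any seed.  The
enumeration cap (default 1000) guards against poorly specified inputs
whose world counts explode; hitting it sets an explicit overflow flag.

`oracle_worlds()` is a deliberately naive cross-check used throughout
the tests: it enumerates *every* subset of candidate regions as a bit
mask (feasible up to 22 regions), filters, projects, and deduplicates.
The two implementations share only the region construction and the
zone-to-relation lookup; agreement on all embedded fixtures and on
seeded random problems is part of the test suite.

## MIR and the deduced/inferred boundary

With a non-empty world set, `compute_mir()` records, for each ordered
cross-taxonomy pair (more recent taxonomy first), the union of
relations realized across worlds.  `classify_mir()` labels entries:

* `input` — the pair was asserted with a singleton relation;
* `deduced` — a singleton relation already follows from
  path-consistency closure over the input articulations plus the tree
  edges (contributed as parent `{equals, includes}` child), with no
  coverage or sibling reasoning;
* `inferred` — everything else, i.e. entries that genuinely need the
  model-based (coverage-aware) world semantics.

The source use case never defines "immediately deducible" formally;
this closure criterion was fixed because it reproduces the published
4 deduced / 4 inferred split of the ostensive 1936/1954 alignment.  For
other alignments the published splits use an unstated convention and
are not reproduced; `mir_summary()` counts `input` entries as deduced.

```{r}
p <- perelleschus(1, "OST")
mir_summary(classify_mir(p, compute_mir(p, enumerate_worlds(p))))
```

## Sufficiency, questions, repair

`sufficient_subset()` performs greedy elimination in file order,
dropping every articulation whose removal leaves the world set (by
relation-assignment identity) unchanged; the result is minimal under
deletion but not guaranteed globally minimum, matching the
"sufficient, not minimum" reading of the source annotations.  On the
ostensive 1936/1954 input the greedy pass keeps only the species-level
congruence: sibling disjointness already entails the two exclusion
articulations, so the published three-articulation sufficient set is
itself reducible.

`next_question()` proposes the cross-taxonomy pair with the largest
realized relation set (ties broken lexicographically); asserting each
of its possible answers partitions the world set, which is the
decision-tree loop for making an ambiguous alignment expressive.

`repair_options()` explains inconsistent inputs by breadth-first search
over articulation subsets up to `max_size` (default 3 — diagnosis
degrades when many erroneous articulations are present at once),
reporting *all* minimal correction sets, verified exhaustively.  Only
articulations are candidates: relaxing coverage or adding implied
children is expert input modulation, not automated repair.  Because the
search is complete, it can report more options than an expert would
accept — for the 1936/1954 overlap reading without an implied child it
finds both "drop the genus overlap" and "drop the species congruence",
and deciding between them is the expert's job.

## Merge graphs

`congruence_clusters()` groups concepts that are congruent in a chosen
world; `containment_graph()` draws the transitively reduced proper
inclusion order on clusters plus undirected overlap edges; and
`merge_concept_graph()` resolves each overlapping cluster pair (A, B)
into the occupied regions among `A\B`, `A*B` (operands in lexicographic
order), and `B\A`.  Region existence is read off the world's occupied
regions, not off label algebra, so an empty region is never drawn, and
a region whose extension coincides with an existing node (for example
an implied child that *is* the unique-to-1936 part of a genus overlap)
becomes an alias label on that node rather than a duplicate.  Cascading
overlaps are resolved pairwise.  `write_dot()` renders either graph
with the conventional encoding: grey boxes for clusters present in both
taxonomies, yellow octagons for T1-only, green rectangles for T2-only.

## The random generator

`random_problem()` exists for property testing, and its construction
mirrors the semantics exactly: it grows two random trees (`n1`, `n2`
concepts, branching bound `max_children`), plants a world by drawing a
Bernoulli(0.5) occupancy over the candidate regions and then repairing
empty rows/columns so non-emptiness holds, derives every true
leaf-pair relation from the planted world, and emits a `density`
fraction of them as singleton articulations.  The planted world
satisfies the emitted problem by construction, so solver soundness is
testable (planted ∈ enumerated) without trusting the solver.  What the
generator does *not* emulate: disjunctive expert uncertainty, `nc`
flags, implied children, and the deep (5+ level) hierarchies of real
revisions — tests on generated data therefore exercise the constraint
semantics, not the expert-workflow phenomena, which the embedded
use-case fixtures cover instead.  Test problem sizes were chosen at 3-5
concepts per taxonomy so the 2^n oracle stays exact; the solver itself
handles the path-product scale of real inputs.

## Numerical and design choices

* The composition table is frozen from a brute-force enumeration over
  non-empty subsets of a 4-element universe (4 elements suffice to
  realize every RCC-5 composition possibility); the tests re-derive it
  independently.
* The empty relation set is representable but illegal as input; it is
  reserved as the closure's inconsistency signal.
* World keys use a canonical lexicographic pair ordering, so two
  problems declaring the same concepts in different orders have
  comparable world sets (this is what makes the parse/render round-trip
  property well defined).
* Degenerate inputs: single-concept taxonomies are legal (`concepts`
  argument); empty articulation lists are legal and simply enumerate
  all constraint-respecting worlds; structural errors are reported as
  a complete list of diagnostics by `validate_problem()` rather than
  thrown one at a time.
* Alignments 1 and 2 of the use case are embedded verbatim from the
  published running text; alignments 3-6 require their externally
  distributed input files, and the loader says so explicitly rather
  than approximating them.

## Limitations

Exactly two taxonomies per run; strict rooted trees (no multiple
parents); intensional (property-based) readings are represented only
through user-edited inputs (implied children, adjusted articulations),
never inferred from character data; and the exhaustive repair search is
practical only for small numbers of simultaneously erroneous
articulations.
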