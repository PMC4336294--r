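# taxalign

Logic-based alignment of biological taxonomies related by RCC-5
articulations.

## What it is for

Classifications and phylogenies change: a revision moves species between
genera, adds newly described species, or keeps a name while redefining
its circumscription. `taxalign` is for systematists and biodiversity
informaticians who need to state *precisely* how the taxonomic concepts
of two treatments relate, and to let a reasoner do the bookkeeping.
Concepts are individuated by source ("name sec. author"), and an expert
asserts **RCC-5** articulations between concepts of the two input trees:
congruence (`==`), proper inclusion (`>`), inverse proper inclusion
(`<`), overlap (`><`), exclusion (`|`), or a disjunction of these (the
five base relations generate a 32-member articulation lattice).
Together with three taxonomic constraints — non-emptiness, sibling
disjointness, and per-parent relaxable coverage — the input either
admits **possible worlds** (complete, consistent alignments) or is
logically inconsistent.

The package:

* decides consistency and enumerates all possible worlds
  (`is_consistent()`, `enumerate_worlds()`), with an independent
  brute-force oracle for small instances (`oracle_worlds()`);
* computes the **maximally informative relations** (MIR): the tightest
  entailed relation set for every cross-taxonomy concept pair, split
  into input / immediately deducible / inferred entries
  (`compute_mir()`, `classify_mir()`);
* finds deletion-minimal sufficient inputs (`sufficient_subset()`) and
  proposes the most informative disambiguation question
  (`next_question()`);
* diagnoses inconsistent inputs by listing all minimal sets of
  removable articulations (`repair_options()`);
* builds containment-with-overlap and merge-concept (Euler region)
  graphs from any world and renders them as DOT
  (`containment_graph()`, `merge_concept_graph()`, `write_dot()`);
* reads and writes a plain-text problem format (`parse_problem()`,
  `render_problem()`) and ships a CLI (`exec/taxalign`,
  `euler_cli()`);
* embeds the classic *Perelleschus* flower-weevil use case
  (`perelleschus()`) and a seeded random generator with planted
  solutions (`random_problem()`).

## Worked example

The 1936/1954 alignment of the use case: Günther (1936) placed one
species in an expanded *Elleschus*; Voss (1954) created *Perelleschus*
for that species plus two new ones.

```r
library(taxalign)

p <- perelleschus(1, "OST")   # ostensive reading, as published
worlds <- enumerate_worlds(p)
length(worlds)
#> [1] 1

mir <- classify_mir(p, compute_mir(p, worlds))
mir_summary(mir)
#>  deduced inferred    total
#>        4        4        8

cat(write_mir(mir))
#> left,relation,right,provenance,resolved
#> 1954.Pcarlud,equals,1936.ELLcarlud,input,true
#> 1954.Prectir,disjoint,1936.ELLcarlud,input,true
#> 1954.Psubcin,disjoint,1936.ELLcarlud,input,true
#> 1954.PER,includes,1936.ELLcarlud,deduced,true
#> 1954.Pcarlud,equals,1936.ELL,inferred,true
#> 1954.PER,includes,1936.ELL,inferred,true
#> 1954.Prectir,disjoint,1936.ELL,inferred,true
#> 1954.Psubcin,disjoint,1936.ELL,inferred,true
```

One world exists: of its 8 MIR entries, 4 follow by pure relational
closure from the input (the three asserted species articulations plus
`1954.PER > 1936.ELLcarlud`), while the 4 entries involving `1936.ELL`
need the coverage semantics — the monotypic 1936 genus collapses onto
its single species, so the reasoner infers `1954.PER > 1936.ELL` and
places `1936.ELL` in a congruence cluster with `1936.ELLcarlud` and
`1954.Pcarlud`.

Underspecifying the overlap reading shows ambiguity growing:

```r
length(enumerate_worlds(perelleschus(1, "underspec_L1")))
#> [1] 8
length(enumerate_worlds(perelleschus(1, "underspec_L2")))
#> [1] 17
```

From the shell, using the example problem files shipped under
`inst/extdata/`:

```sh
f=$(Rscript -e 'cat(system.file("extdata", "alignment1_ost.txt", package = "taxalign"))')
Rscript exec/taxalign check "$f"
#> consistent, 1 possible world
Rscript exec/taxalign mir "$f" --out=out
Rscript exec/taxalign merge "$f" --out=out

b=$(Rscript -e 'cat(system.file("extdata", "alignment1_inconsistent.txt", package = "taxalign"))')
Rscript exec/taxalign repair "$b"
#> repair option 1: remove 1 articulation(s) -> 2 world(s)
#>   [1954.Pcarlud equals 1936.ELLcarlud]
#> repair option 2: remove 1 articulation(s) -> 1 world(s)
#>   [1954.PER overlaps 1936.ELL]
```

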