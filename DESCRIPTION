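Package: taxalign
Title: Logic-Based Alignment of Biological Taxonomies with RCC-5
    Articulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Aligns two taxonomies (classifications or phylogenies) whose
    concepts are related by expert-asserted Region Connection Calculus
    (RCC-5) articulations: congruence, proper inclusion, inverse proper
    inclusion, overlap, and exclusion, possibly as disjunctions.  Given the
    two concept hierarchies, the articulations, and taxonomic constraints
    (non-emptiness, sibling disjointness, and per-parent relaxable
    coverage), the package decides logical consistency, enumerates all
    possible-world alignments, computes the maximally informative relations
    (MIR) entailed for every cross-taxonomy concept pair, diagnoses
    inconsistent inputs by listing minimal sets of removable articulations,
    finds minimal sufficient inputs, proposes disambiguation questions, and
    renders containment-with-overlap and merge-concept (Euler region)
    graphs in DOT format.  Includes a plain-text problem-file format, a
    command-line driver, embedded example alignments, and a seeded random
    problem generator with planted solutions for property testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
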