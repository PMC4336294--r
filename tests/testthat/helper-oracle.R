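# Independent set-model oracle for the RCC-5 algebra, plus small problem
# builders shared across the tests.

# relation between two non-empty finite sets
set_relation <- function(A, B) {
  l <- length(setdiff(A, B)) > 0L
  s <- length(intersect(A, B)) > 0L
  r <- length(setdiff(B, A)) > 0L
  if (!l && s && !r) "equals"
  else if (l && s && !r) "includes"
  else if (!l && s && r) "is_included_in"
  else if (l && s && r) "overlaps"
  else "disjoint"
}

# brute-force composition: all triples of non-empty subsets of 1..4
oracle_compose <- function(r1, r2) {
  U <- 1:4
  subsets <- Filter(length, lapply(1:15, function(m) {
    U[bitwAnd(m, 2^(U - 1)) > 0]
  }))
  out <- character(0)
  for (A in subsets) for (B in subsets) {
    if (set_relation(A, B) != r1) next
    for (C in subsets) {
      if (set_relation(B, C) == r2) out <- union(out, set_relation(A, C))
    }
  }
  as_rcc5_set(out)
}

world_keys <- function(worlds) sort(vapply(worlds, `[[`, "", "key"))

# two single-concept taxonomies with one articulation
toy_problem <- function(relation) {
  alignment_problem(
    taxonomy("A", list(), concepts = "x"),
    taxonomy("B", list(), concepts = "y"),
    list(articulation("B.y", relation, "A.x"))
  )
}

# the alignment-1 variant discussed for inconsistency: genus-level
# articulation `rel` but no implied child under 1936.ELL
a1_variant <- function(rel) {
  alignment_problem(
    taxonomy("1936", list(ELL = "ELLcarlud")),
    taxonomy("1954", list(PER = c("Pcarlud", "Prectir", "Psubcin"))),
    list(articulation("1954.Pcarlud", "equals", "1936.ELLcarlud"),
         articulation("1954.Prectir", "disjoint", "1936.ELLcarlud"),
         articulation("1954.Psubcin", "disjoint", "1936.ELLcarlud"),
         articulation("1954.PER", rel, "1936.ELL"))
  )
}

# reduced genus-transfer pattern behind the third use-case alignment:
# the 2001 revision moves P. subcinctus into Phyllotrox, whose coverage
# by its single listed child makes the genus-level overlap inconsistent
a3_pattern <- function() {
  alignment_problem(
    taxonomy("1986", list(PER = c("Pcarlud", "Prectir", "Psubcin"))),
    taxonomy("2001", list(DER = c("PER", "PHY"),
                          PER = c("Pcarlud", "Prectir"),
                          PHY = "PHYsubcin")),
    list(articulation("2001.Pcarlud", "equals", "1986.Pcarlud"),
         articulation("2001.Prectir", "equals", "1986.Prectir"),
         articulation("2001.PHYsubcin", "equals", "1986.Psubcin"),
         articulation("2001.PHY", "overlaps", "1986.PER"))
  )
}
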