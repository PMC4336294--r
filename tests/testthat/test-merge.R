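test_that("congruence clusters partition the concepts with correct provenance", {
  p2 <- perelleschus(2)
  cl2 <- congruence_clusters(enumerate_worlds(p2)[[1]], "1954", "1986")
  expect_length(cl2, 4L)
  expect_true(all(vapply(cl2, `[[`, "", "provenance") == "both"))
  expect_setequal(unlist(lapply(cl2, `[[`, "members")),
                  c(paste0("1954.", c("PER", "Pcarlud", "Prectir",
                                      "Psubcin")),
                    paste0("1986.", c("PER", "Pcarlud", "Prectir",
                                      "Psubcin"))))

  p1 <- perelleschus(1, "OST")
  cl1 <- congruence_clusters(enumerate_worlds(p1)[[1]], "1936", "1954")
  mem <- lapply(cl1, `[[`, "members")
  hit <- Filter(function(m) "1936.ELL" %in% m, mem)
  expect_length(hit, 1L)
  expect_setequal(hit[[1]],
                  c("1936.ELL", "1936.ELLcarlud", "1954.Pcarlud"))

  # a world with no congruent pairs: all singleton clusters
  pt <- toy_problem("overlaps")
  clt <- congruence_clusters(enumerate_worlds(pt)[[1]], "A", "B")
  expect_length(clt, 2L)
  expect_true(all(lengths(lapply(clt, `[[`, "members")) == 1L))
})

test_that("containment graphs carry reduced inclusion edges and overlap edges", {
  p <- perelleschus(1, "INT_OST")
  w <- enumerate_worlds(p)[[1]]
  g <- containment_graph(p, w)
  expect_identical(nrow(g$overlap), 1L)
  expect_setequal(c(g$overlap$a, g$overlap$b), c("1936.ELL", "1954.PER"))

  # congruent alignment: tree isomorphic to either input, no overlap
  p2 <- perelleschus(2)
  g2 <- containment_graph(p2, enumerate_worlds(p2)[[1]])
  expect_identical(nrow(g2$overlap), 0L)
  expect_length(g2$nodes, 4L)
  expect_identical(nrow(g2$inclusion), 3L)  # star: genus over 3 species

  # transitive reduction on a chain: two edges survive
  pc <- alignment_problem(
    taxonomy("X", data.frame(parent = c("a", "b"), child = c("b", "c")),
             coverage_off = c("a", "b")),
    taxonomy("Y", list(), concepts = "z"),
    list(articulation("Y.z", "equals", "X.c"))
  )
  wc <- enumerate_worlds(pc)
  # pick a world where a > b > c strictly
  strict <- Filter(function(w) {
    world_relation(w, "X.a", "X.b") == "includes" &&
      world_relation(w, "X.b", "X.c") == "includes"
  }, wc)
  expect_gte(length(strict), 1L)
  gc <- containment_graph(pc, strict[[1]])
  expect_identical(nrow(gc$inclusion), 2L)
  expect_false(any(gc$inclusion$from == gc$inclusion$to))
})

test_that("merge-concept graphs resolve overlaps into labelled Euler regions", {
  p <- perelleschus(1, "INT_OST")
  w <- enumerate_worlds(p)[[1]]
  g <- merge_concept_graph(p, w)
  labels <- unlist(lapply(g$nodes, `[[`, "labels"))
  expect_true("1936.ELL*1954.PER" %in% labels)
  expect_true("1936.ELL\\1954.PER" %in% labels)
  expect_true("1954.PER\\1936.ELL" %in% labels)
  # the unique-to-1936 region coincides with the implied child
  icnode <- Filter(function(nd) "1936.ELL\\1954.PER" %in% nd$labels,
                   g$nodes)[[1]]
  expect_true("1936.ELL_IC" %in% icnode$labels)
  # overlaps are fully resolved: no overlap edges remain
  expect_identical(nrow(g$overlap), 0L)
  # node extensions partition the occupied regions at leaf level: the
  # union of minimal-node extensions covers every occupied region once
  ids <- vapply(g$nodes, `[[`, "", "id")
  ext <- lapply(g$nodes, `[[`, "extension")
  names(ext) <- ids
  is_leaf <- vapply(ids, function(i) !i %in% g$inclusion$from, logical(1))
  leafext <- unlist(ext[is_leaf], use.names = FALSE)
  expect_identical(anyDuplicated(leafext), 0L)
  expect_setequal(leafext, seq_along(w$regions))
})

test_that("without overlaps the merge-concept graph equals the containment graph", {
  for (p in list(perelleschus(1, "OST"), perelleschus(2))) {
    w <- enumerate_worlds(p)[[1]]
    gc <- containment_graph(p, w)
    gm <- merge_concept_graph(p, w)
    expect_identical(vapply(gm$nodes, `[[`, "", "id"),
                     vapply(gc$nodes, `[[`, "", "id"))
    expect_identical(gm$inclusion, gc$inclusion)
    expect_identical(nrow(gm$overlap), 0L)
  }
})

test_that("a two-overlapping-parents toy resolves three regions per overlap", {
  p <- parse_problem(c(
    "taxonomy 1 one", "(A B C)", "",
    "taxonomy 2 two", "(D E F)", "",
    "articulation toy",
    "[2.E equals 1.B]",
    "[2.F disjoint 1.B]",
    "[2.F disjoint 1.C]",
    "[2.D overlaps 1.A]"
  ))
  w <- enumerate_worlds(p)
  expect_length(w, 1L)
  g <- merge_concept_graph(p, w[[1]])
  labels <- unlist(lapply(g$nodes, `[[`, "labels"))
  expect_true(any(grepl("\\*", labels)))
  expect_true(any(grepl("\\\\2.D", labels)))
  expect_true(any(grepl("^2.D\\\\", labels)))
  expect_identical(nrow(g$overlap), 0L)
})
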