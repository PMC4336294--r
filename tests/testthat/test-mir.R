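test_that("MIR covers all ordered cross-taxonomy pairs, T2 concept first", {
  p <- perelleschus(1, "OST")
  mir <- compute_mir(p, enumerate_worlds(p))
  expect_identical(nrow(mir), 2L * 4L)
  expect_true(all(startsWith(mir$left, "1954.")))
  expect_true(all(startsWith(mir$right, "1936.")))
  expect_true(all(mir$resolved))
  # the genus pair resolves to proper inclusion
  k <- which(mir$left == "1954.PER" & mir$right == "1936.ELL")
  expect_identical(mir$realized[[k]], "includes")

  p12 <- perelleschus(1, "INT_OST")
  expect_identical(nrow(compute_mir(p12, enumerate_worlds(p12))), 3L * 4L)
  p2 <- perelleschus(2)
  mir2 <- compute_mir(p2, enumerate_worlds(p2))
  expect_identical(nrow(mir2), 4L * 4L)
  expect_true(all(mir2$resolved))
})

test_that("MIR is undefined for an inconsistent problem", {
  expect_error(compute_mir(perelleschus(1, "OST"), list()), "inconsistent")
})

test_that("single world implies singleton realized sets everywhere", {
  p <- perelleschus(1, "INT")
  mir <- compute_mir(p, enumerate_worlds(p))
  expect_true(all(lengths(mir$realized) == 1L))
})

test_that("realized sets stay within the closure-derived bound", {
  p <- perelleschus(1, "underspec_L1")
  mir <- compute_mir(p, enumerate_worlds(p))
  left <- vapply(p$articulations, `[[`, "", "left")
  right <- vapply(p$articulations, `[[`, "", "right")
  relation <- lapply(p$articulations, `[[`, "relation")
  for (tax in list(p$t1, p$t2)) {
    left <- c(left, paste(tax$id, tax$edges$parent, sep = "."))
    right <- c(right, paste(tax$id, tax$edges$child, sep = "."))
    relation <- c(relation,
                  rep(list(c("equals", "includes")), nrow(tax$edges)))
  }
  cl <- rcc5_closure(left, right, relation)
  ck <- paste(cl$relations$left, cl$relations$right, sep = "|")
  for (k in seq_len(nrow(mir))) {
    cset <- cl$relations$relation[[match(paste(mir$left[k], mir$right[k],
                                               sep = "|"), ck)]]
    expect_true(all(mir$realized[[k]] %in% cset))
  }
})

test_that("provenance classes partition the MIR with input inside deduced", {
  p <- perelleschus(1, "OST")
  mir <- classify_mir(p, compute_mir(p, enumerate_worlds(p)))
  expect_true(all(mir$provenance %in% c("input", "deduced", "inferred")))
  s <- mir_summary(mir)
  expect_identical(unname(s["deduced"] + s["inferred"]), nrow(mir))
  # the published split: 4 immediately deducible (3 of them input), 4
  # inferred, the latter exactly the pairs involving the 1936 genus
  expect_identical(unname(s["deduced"]), 4L)
  expect_identical(unname(s["inferred"]), 4L)
  expect_identical(sum(mir$provenance == "input"), 3L)
  k <- which(mir$left == "1954.PER" & mir$right == "1936.ELLcarlud")
  expect_identical(mir$provenance[k], "deduced")
  expect_setequal(mir$right[mir$provenance == "inferred"], "1936.ELL")
})

test_that("a pair left disjunctive by the closure but world-resolved is inferred", {
  # no articulations at all: everything must be inferred
  p <- alignment_problem(taxonomy("A", list(), concepts = "x"),
                         taxonomy("B", list(), concepts = "y"), list())
  mir <- classify_mir(p, compute_mir(p, enumerate_worlds(p)))
  expect_identical(unique(mir$provenance), "inferred")
})

test_that("sufficient subsets preserve the world set and are deletion-minimal", {
  for (prob in list(perelleschus(1, "OST"), perelleschus(1, "INT_OST"),
                    perelleschus(2))) {
    keep <- sufficient_subset(prob)
    trimmed <- prob
    trimmed$articulations <- prob$articulations[keep]
    expect_identical(world_keys(enumerate_worlds(trimmed)),
                     world_keys(enumerate_worlds(prob)))
    # minimal under deletion: dropping any retained articulation changes
    # the world set
    for (k in seq_along(keep)) {
      p2 <- prob
      p2$articulations <- prob$articulations[keep[-k]]
      expect_false(identical(world_keys(enumerate_worlds(p2)),
                             world_keys(enumerate_worlds(prob))))
    }
  }
})

test_that("a lone load-bearing articulation is retained and duplicates dropped", {
  base <- toy_problem("overlaps")
  expect_identical(as.integer(sufficient_subset(base)), 1L)
  dup <- base
  dup$articulations <- c(base$articulations, base$articulations)
  expect_length(sufficient_subset(dup), 1L)
})

test_that("the next question targets the most ambiguous pair and partitions worlds", {
  p <- perelleschus(1, "underspec_L1")
  worlds <- enumerate_worlds(p)
  q <- next_question(p, worlds)
  expect_identical(q$relations, c("is_included_in", "overlaps", "disjoint"))
  expect_true(q$right %in% c("1936.ELL", "1936.ELL_IC"))
  # answering with each realized relation partitions the world set
  total <- 0L
  seen <- character(0)
  for (r in q$relations) {
    p2 <- p
    p2$articulations <- c(p$articulations,
                          list(articulation(q$left, r, q$right)))
    sub <- enumerate_worlds(p2)
    total <- total + length(sub)
    seen <- c(seen, world_keys(sub))
  }
  expect_identical(total, length(worlds))
  expect_setequal(seen, world_keys(worlds))

  # single world: no question
  p1 <- perelleschus(1, "OST")
  expect_null(next_question(p1, enumerate_worlds(p1)))

  # two worlds differing in one pair: that pair is asked
  ptoy <- toy_problem(c("equals", "overlaps"))
  wt <- enumerate_worlds(ptoy)
  expect_length(wt, 2L)
  qt <- next_question(ptoy, wt)
  expect_identical(qt$left, "B.y")
  expect_identical(qt$right, "A.x")
  expect_identical(qt$relations, c("equals", "overlaps"))
})
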