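test_that("candidate regions pair per-taxonomy chains and respect the bound", {
  # single concept vs single concept: A only, B only, both
  p <- alignment_problem(taxonomy("A", list(), concepts = "x"),
                         taxonomy("B", list(), concepts = "y"), list())
  expect_length(candidate_regions(p), 3L)

  p1 <- perelleschus(1, "OST")
  regs <- candidate_regions(p1)
  # (paths1 + 1) * (paths2 + 1) - 1: one 1936 chain, three 1954 chains
  expect_length(regs, (1L + 1L) * (3L + 1L) - 1L)
  # every pattern restricted to one taxonomy is upward closed
  for (r in regs) {
    for (tax in list(p1$t1, p1$t2)) {
      mem <- sub("^[^.]+\\.", "", grep(paste0("^", tax$id, "\\."), r,
                                       value = TRUE))
      if (length(mem) == 0L) next
      par <- setdiff(tax$edges$parent[tax$edges$child %in% mem],
                     mem)
      expect_length(par, 0L)
    }
  }
})

test_that("relaxing sibling disjointness strictly enlarges the region set", {
  p <- perelleschus(1, "OST")
  prelax <- p
  prelax$toggles$sibling_disjointness <- FALSE
  expect_gt(length(candidate_regions(prelax)),
            length(candidate_regions(p)))
})

test_that("non-coverage parents admit regions beyond their children", {
  # the genus PHY lists a single species but is flagged as not covered by
  # it, so it may overlap a genus whose extension reaches beyond that
  # shared species; with full coverage the same overlap is contradictory
  pnc <- parse_problem(c("taxonomy 2001 t2001", "(PHY PHYsubcin nc)", "",
                         "taxonomy 1986 t1986", "(PER Pcarlud Psubcin)",
                         "", "articulation a",
                         "[2001.PHYsubcin equals 1986.Psubcin]",
                         "[2001.PHY overlaps 1986.PER]"))
  # with coverage relaxed on PHY the genus overlap is satisfiable
  expect_true(as.logical(is_consistent(pnc)))
  # with full coverage it is not
  pcov <- pnc
  pcov$t1$coverage_off <- character(0)
  expect_false(as.logical(is_consistent(pcov)))
})

test_that("consistency matches the use-case outcomes", {
  expect_true(as.logical(is_consistent(perelleschus(1, "OST"))))
  w <- attr(is_consistent(perelleschus(1, "OST")), "witness")
  expect_s3_class(w, "euler_world")
  # overlap without an implied child is inconsistent
  expect_false(as.logical(is_consistent(a1_variant("overlaps"))))
  # reciprocal proper inclusion across taxonomies is inconsistent
  p <- alignment_problem(taxonomy("A", list(), concepts = "x"),
                         taxonomy("B", list(), concepts = "y"),
                         list(articulation("B.y", "includes", "A.x"),
                              articulation("B.y", "is_included_in",
                                           "A.x")))
  expect_false(as.logical(is_consistent(p)))
})

test_that("world counts reproduce the published underspecification ladder", {
  expect_length(enumerate_worlds(perelleschus(1, "OST")), 1L)
  expect_length(enumerate_worlds(perelleschus(1, "INT_OST")), 1L)
  expect_length(enumerate_worlds(perelleschus(1, "INT")), 1L)
  expect_length(enumerate_worlds(perelleschus(1, "underspec_L1")), 8L)
  expect_length(enumerate_worlds(perelleschus(1, "underspec_L2")), 17L)
  expect_length(enumerate_worlds(perelleschus(2)), 1L)
})

test_that("every returned world satisfies the articulations and constraints", {
  for (reading in c("underspec_L1", "underspec_L2")) {
    p <- perelleschus(1, reading)
    for (w in enumerate_worlds(p)) {
      for (a in p$articulations) {
        expect_true(world_relation(w, a$left, a$right) %in% a$relation)
      }
      # non-emptiness: every concept occupies at least one region
      for (q in w$concepts) {
        expect_true(any(vapply(w$regions, function(r) q %in% r,
                               logical(1))))
      }
      # sibling disjointness: no region holds two siblings
      for (tax in list(p$t1, p$t2)) {
        sibs <- split(tax$edges$child, tax$edges$parent)
        for (ss in sibs) {
          for (r in w$regions) {
            expect_lte(sum(paste(tax$id, ss, sep = ".") %in% r), 1L)
          }
        }
      }
    }
  }
})

test_that("removing articulations never shrinks the world set", {
  p <- perelleschus(1, "INT_OST")
  n_full <- length(enumerate_worlds(p))
  for (k in seq_along(p$articulations)) {
    p2 <- p
    p2$articulations <- p$articulations[-k]
    expect_gte(length(enumerate_worlds(p2)), n_full)
  }
})

test_that("solver and brute-force oracle agree on the embedded fixtures", {
  for (reading in c("OST", "INT_OST", "INT", "underspec_L1",
                    "underspec_L2")) {
    p <- perelleschus(1, reading)
    expect_identical(world_keys(enumerate_worlds(p)),
                     world_keys(oracle_worlds(p)), info = reading)
  }
  p2 <- perelleschus(2)
  expect_identical(world_keys(enumerate_worlds(p2)),
                   world_keys(oracle_worlds(p2)))
  # and on an inconsistent input both return none
  bad <- a1_variant("overlaps")
  expect_length(oracle_worlds(bad), 0L)
  expect_length(enumerate_worlds(bad), 0L)
})

test_that("solver and oracle agree on 100 seeded random problems", {
  for (s in 1:100) {
    rp <- random_problem(n1 = 3L + s %% 2L, n2 = 3L + (s %/% 2L) %% 2L,
                         density = ((s %% 4L) + 1L) / 4, seed = s)
    expect_identical(world_keys(enumerate_worlds(rp$problem,
                                                 cap = 100000L)),
                     world_keys(oracle_worlds(rp$problem)),
                     info = paste("seed", s))
  }
})

test_that("the planted world is always recovered", {
  for (s in 1:200) {
    rp <- random_problem(n1 = 3L + s %% 3L, n2 = 3L + (s %/% 3L) %% 3L,
                         density = 1 - (s %% 2L) / 4, seed = 1000L + s)
    keys <- vapply(enumerate_worlds(rp$problem, cap = 100000L), `[[`, "",
                   "key")
    expect_true(rp$planted$key %in% keys, label = paste("seed", s))
  }
})

test_that("the enumeration cap sets the overflow flag and truncates", {
  p <- perelleschus(1, "underspec_L2")
  res <- enumerate_worlds(p, cap = 5L)
  expect_length(res, 5L)
  expect_true(attr(res, "overflow"))
  full <- enumerate_worlds(p)
  expect_false(attr(full, "overflow"))
})

test_that("the oracle refuses oversized instances", {
  rp <- random_problem(n1 = 12L, n2 = 12L, max_children = 3L,
                       density = 1, seed = 7L)
  expect_error(oracle_worlds(rp$problem), "too large")
})

test_that("world identity is the relation mapping, not the occupied set", {
  # a 3-leaf vs 1-leaf problem where distinct occupancies project equal:
  # with no articulations the T2-only cells can vary without changing
  # any pairwise relation only when they are forced; here we check the
  # deduplication by comparing against the oracle's projected count
  p <- perelleschus(1, "underspec_L2")
  keys <- world_keys(enumerate_worlds(p))
  expect_identical(anyDuplicated(keys), 0L)
})
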