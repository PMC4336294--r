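# Embedded example alignment problems (the Perelleschus weevil use case,
# 1936-2013 classification history) and a seeded random problem generator
# with a planted solution for property testing.

.perelleschus_1936 <- function(implied_child = FALSE) {
  kids <- c("ELLcarlud", if (implied_child) "ELL_IC")
  taxonomy("1936", list(ELL = kids), display_name = "Guenther_1936")
}

.perelleschus_1954 <- function() {
  taxonomy("1954", list(PER = c("Pcarlud", "Prectir", "Psubcin")),
           display_name = "Voss_1954")
}

.perelleschus_1986 <- function() {
  taxonomy("1986", list(PER = c("Pcarlud", "Prectir", "Psubcin")),
           display_name = "WibmerOBrien_1986")
}

.species_arts_1 <- function() {
  list(articulation("1954.Pcarlud", "equals", "1936.ELLcarlud"),
       articulation("1954.Prectir", "disjoint", "1936.ELLcarlud"),
       articulation("1954.Psubcin", "disjoint", "1936.ELLcarlud"))
}

#' Embedded Perelleschus use-case alignment problems
#'
#' The use case tracks the classification history of the flower-weevil
#' genus concept Perelleschus (and its 1936 predecessor Elleschus) across
#' six taxonomies published 1936-2013.  Alignments 1 (1936/1954) and 2
#' (1954/1986) are embedded in full; their taxonomies and articulations
#' are small enough to state completely.  Alignments 3-6 involve the
#' 24-53-concept phylogenies of 1986-2013 whose complete articulation
#' lists are distributed as separate data files, so requesting them
#' signals that an external problem file (loadable via [parse_problem()])
#' is needed.
#'
#' Readings for alignment 1:
#' \describe{
#'   \item{`OST`}{strictly ostensive: the two taxonomies as published
#'     (6 concepts) with the three species-level articulations plus the
#'     disjunctive genus-level articulation
#'     `1954.PER {includes overlaps is_included_in} 1936.ELL`.}
#'   \item{`INT_OST`}{overlap reading: an implied child `1936.ELL_IC` is
#'     added under `1936.ELL`, the genus articulation is restricted to
#'     `overlaps`, and `1954.PER disjoint 1936.ELL_IC` is asserted
#'     (7 concepts, 5 articulations).}
#'   \item{`INT`}{intensional reading: implied child plus
#'     `1954.PER is_included_in 1936.ELL` (4 articulations).}
#'   \item{`underspec_L1`}{the `INT_OST` input without the
#'     `1954.PER disjoint 1936.ELL_IC` articulation (8 possible worlds).}
#'   \item{`underspec_L2`}{additionally without the genus-level overlap
#'     articulation (17 possible worlds).}
#' }
#' Alignment 2 (`INT_OST`, the default) aligns the congruent 1954 and
#' 1986 classifications: three species-level `equals` articulations plus
#' the redundant genus-level `equals`.
#'
#' @param alignment Integer 1-6.
#' @param reading One of `"OST"`, `"INT"`, `"INT_OST"`,
#'   `"underspec_L1"`, `"underspec_L2"` (alignment 1) or `"INT_OST"`
#'   (alignment 2).
#' @return An `euler_problem`.
#' @export
#' @examples
#' p <- perelleschus(1, "OST")
#' length(enumerate_worlds(p))
perelleschus <- function(alignment,
                         reading = c("INT_OST", "OST", "INT",
                                     "underspec_L1", "underspec_L2")) {
  reading <- match.arg(reading)
  stopifnot(length(alignment) == 1L, alignment %in% 1:6)
  if (alignment >= 3L) {
    stop("alignment ", alignment, " is not embedded: its full ",
         "articulation list lives in an external dataset file; convert ",
         "it to the problem-file format and load it with parse_problem()",
         call. = FALSE)
  }
  if (alignment == 2L) {
    if (reading != "INT_OST") {
      stop("alignment 2 is embedded only in its INT_OST reading",
           call. = FALSE)
    }
    arts <- list(
      articulation("1986.Pcarlud", "equals", "1954.Pcarlud"),
      articulation("1986.Prectir", "equals", "1954.Prectir"),
      articulation("1986.Psubcin", "equals", "1954.Psubcin"),
      articulation("1986.PER", "equals", "1954.PER")
    )
    return(alignment_problem(.perelleschus_1954(), .perelleschus_1986(),
                             arts))
  }
  t2 <- .perelleschus_1954()
  if (reading == "OST") {
    arts <- c(.species_arts_1(),
              list(articulation("1954.PER",
                                c("includes", "overlaps",
                                  "is_included_in"),
                                "1936.ELL")))
    return(alignment_problem(.perelleschus_1936(FALSE), t2, arts))
  }
  t1 <- .perelleschus_1936(TRUE)
  arts <- switch(
    reading,
    INT_OST = c(.species_arts_1(),
                list(articulation("1954.PER", "overlaps", "1936.ELL"),
                     articulation("1954.PER", "disjoint", "1936.ELL_IC"))),
    INT = c(.species_arts_1(),
            list(articulation("1954.PER", "is_included_in", "1936.ELL"))),
    underspec_L1 = c(.species_arts_1(),
                     list(articulation("1954.PER", "overlaps",
                                       "1936.ELL"))),
    underspec_L2 = .species_arts_1()
  )
  alignment_problem(t1, t2, arts)
}

# run fn() under a private RNG stream, restoring the caller's stream
.with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

.random_tree <- function(n, max_children) {
  if (n == 1L) {
    return(data.frame(parent = character(0), child = character(0),
                      stringsAsFactors = FALSE))
  }
  labels <- paste0("N", seq_len(n))
  parent <- character(n - 1L)
  nchild <- integer(n)
  for (i in 2:n) {
    open <- which(nchild[seq_len(i - 1L)] < max_children)
    pick <- open[sample.int(length(open), 1L)]
    parent[i - 1L] <- labels[pick]
    nchild[pick] <- nchild[pick] + 1L
  }
  data.frame(parent = parent, child = labels[-1L],
             stringsAsFactors = FALSE)
}

#' Random alignment problem with a planted possible world
#'
#' Builds two random rooted trees, plants a ground-truth world by drawing
#' a random occupancy of the candidate regions (respecting non-emptiness,
#' sibling disjointness, and coverage by construction), derives the true
#' relation of every cross-taxonomy leaf pair from it, and emits a
#' density-chosen subset of those true articulations as the input.  The
#' planted world therefore satisfies the emitted problem, which is
#' consistent by construction.  Identical seed and configuration give
#' byte-identical problems.
#'
#' @param n1,n2 Concept counts of the two taxonomies (at least 1).
#' @param max_children Branching bound of the random trees.
#' @param density Fraction of cross-taxonomy leaf pairs articulated, in
#'   \[0, 1\].
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return List with `problem` (an `euler_problem`) and `planted` (an
#'   `euler_world`).
#' @export
#' @examples
#' rp <- random_problem(4, 4, density = 1, seed = 1)
#' length(enumerate_worlds(rp$problem)) >= 1
random_problem <- function(n1 = 5L, n2 = 5L, max_children = 3L,
                           density = 0.5, seed = 1L) {
  stopifnot(n1 >= 1L, n2 >= 1L, density >= 0, density <= 1)
  .with_seed(seed, function() {
    mk <- function(id, n) {
      tx <- taxonomy(id, .random_tree(n, max_children))
      if (n == 1L) tx$concepts <- "N1"
      tx
    }
    t1 <- mk("T1", n1)
    t2 <- mk("T2", n2)
    problem <- alignment_problem(t1, t2, list())
    rs <- .region_space(problem)
    k1 <- length(rs$p1) - 1L
    k2 <- length(rs$p2) - 1L
    n2p <- length(rs$p2)
    # random occupancy over (pattern1, pattern2) cells, both-empty excluded
    occ <- stats::runif(length(rs$regions)) < 0.5
    cell <- function(i, j) (i - 1L) * n2p + j - 1L  # 1-based pattern idx
    for (i in seq_len(k1) + 1L) {   # every T1 chain somewhere occupied
      row <- vapply(seq_len(n2p), function(j) cell(i, j), integer(1))
      if (!any(occ[row])) occ[cell(i, 1L)] <- TRUE
    }
    for (j in seq_len(k2) + 1L) {   # every T2 chain somewhere occupied
      col <- vapply(seq_len(k1 + 1L), function(i) cell(i, j), integer(1))
      if (!any(occ[col])) occ[cell(1L, j)] <- TRUE
    }
    pt <- .pair_table(rs)
    planted <- .make_world(rs, which(occ), pt$names, pt$zones)
    l1 <- taxonomy_leaves(t1)
    l2 <- taxonomy_leaves(t2)
    pairs <- expand.grid(right = l1, left = l2, stringsAsFactors = FALSE)
    npick <- round(density * nrow(pairs))
    pick <- if (npick > 0L) sort(sample.int(nrow(pairs), npick)) else
      integer(0)
    arts <- lapply(pick, function(k) {
      articulation(pairs$left[k],
                   world_relation(planted, pairs$left[k], pairs$right[k]),
                   pairs$right[k])
    })
    problem$articulations <- arts
    list(problem = problem, planted = planted)
  })
}
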