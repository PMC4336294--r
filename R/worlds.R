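# Possible-world reasoning: candidate Euler regions, consistency,
# enumeration of all distinct alignments, and an independent brute-force
# oracle for small instances.
#
# A region is a set of concepts (from both taxonomies) whose extensions
# jointly contain some points.  Per taxonomy, a region's membership must
# be upward closed, respect sibling disjointness (when on), and respect
# coverage (a covered parent implies one of its children).  Under the
# default constraints the admissible per-taxonomy patterns are exactly the
# root-to-terminal chains (terminal = leaf or non-coverage parent), plus
# the empty pattern.  A possible world is a choice of which candidate
# regions are occupied (non-empty); worlds are identified by the pairwise
# base-relation assignment they induce, not by the occupied set itself.

# terminals: concepts at which a membership chain may stop
.terminals <- function(tax, coverage_on) {
  leaves <- setdiff(tax$concepts, tax$edges$parent)
  term <- if (!coverage_on) {
    tax$concepts
  } else {
    unique(c(leaves, intersect(tax$coverage_off, tax$edges$parent)))
  }
  term[order(match(term, tax$concepts))]
}

# admissible membership patterns for one taxonomy (labels); empty first
.patterns <- function(tax, sibling_disjointness, coverage_on) {
  term <- .terminals(tax, coverage_on)
  chains <- lapply(term, function(t) rev(.tax_chain(tax, t)))
  if (sibling_disjointness) {
    c(list(character(0)), chains)
  } else {
    k <- length(term)
    if (k > 16L) {
      stop("sibling-disjointness off: too many terminals (", k,
           ") for pattern enumeration", call. = FALSE)
    }
    subs <- lapply(seq_len(2^k - 1L), function(m) {
      sel <- bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) > 0L
      u <- unique(unlist(chains[sel], use.names = FALSE))
      u[order(match(u, tax$concepts))]
    })
    c(list(character(0)), subs)
  }
}

.region_space <- function(problem) {
  sib <- problem$toggles$sibling_disjointness
  cov <- problem$toggles$coverage
  p1 <- .patterns(problem$t1, sib, cov)
  p2 <- .patterns(problem$t2, sib, cov)
  n1 <- length(p1)
  n2 <- length(p2)
  regions <- vector("list", n1 * n2 - 1L)
  for (i in seq_len(n1)) {
    q1 <- .qualify(problem$t1, p1[[i]])
    for (j in seq_len(n2)) {
      if (i == 1L && j == 1L) next
      regions[[(i - 1L) * n2 + j - 1L]] <-
        c(q1, .qualify(problem$t2, p2[[j]]))
    }
  }
  concepts <- .problem_concepts(problem)
  inc <- lapply(concepts, function(q) {
    which(vapply(regions, function(r) q %in% r, logical(1)))
  })
  names(inc) <- concepts
  list(regions = regions, concepts = concepts, inc = inc,
       p1 = p1, p2 = p2)
}

#' Candidate Euler regions of an alignment problem
#'
#' Returns every region membership pattern compatible with the two
#' taxonomies and the active constraints: each pattern restricted to one
#' taxonomy is either empty or upward closed, sibling-disjoint (when that
#' toggle is on), and coverage-respecting.  Every region that is occupied
#' in any possible world is drawn from this set.
#'
#' @param problem An `euler_problem`.
#' @return A list of regions, each a character vector of the qualified
#'   concept ids whose extensions contain the region.
#' @export
candidate_regions <- function(problem) {
  stopifnot(inherits(problem, "euler_problem"))
  .region_space(problem)$regions
}

# lookup from (left_only, shared, right_only) to relation / void code,
# indexed by 4*l + 2*s + r + 1
.zone_lookup <- c("void_both", "void_left", "equals", "is_included_in",
                  "void_right", "disjoint", "includes", "overlaps")

.pair_zones <- function(inc, a, b) {
  ia <- inc[[a]]
  ib <- inc[[b]]
  list(l = setdiff(ia, ib), s = intersect(ia, ib), r = setdiff(ib, ia))
}

# build a world object from the set of occupied region indices
.make_world <- function(rs, occ, pair_names, pair_zones) {
  occset <- rep(FALSE, length(rs$regions))
  occset[occ] <- TRUE
  rel <- character(length(pair_zones))
  for (k in seq_along(pair_zones)) {
    z <- pair_zones[[k]]
    rel[k] <- .zone_lookup[4L * any(occset[z$l]) + 2L * any(occset[z$s]) +
                             any(occset[z$r]) + 1L]
  }
  names(rel) <- pair_names
  structure(
    list(concepts = rs$concepts, relations = rel,
         regions = rs$regions[sort(occ)],
         key = paste(rel, collapse = ",")),
    class = "euler_world"
  )
}

#' @export
print.euler_world <- function(x, ...) {
  cat(sprintf("Possible world: %d concepts, %d occupied regions\n",
              length(x$concepts), length(x$regions)))
  invisible(x)
}

# All unordered concept pairs and their zones, in a canonical
# (lexicographic) orientation and order, so that world keys are
# comparable across problems that declare the same concepts in a
# different order.
.pair_table <- function(rs) {
  qq <- rs$concepts
  n <- length(qq)
  nm <- character(0)
  zz <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ab <- sort(c(qq[i], qq[j]))
    nm <- c(nm, paste(ab[1], ab[2], sep = "|"))
    zz[[length(zz) + 1L]] <- .pair_zones(rs$inc, ab[1], ab[2])
  }
  ord <- order(nm)
  list(names = nm[ord], zones = zz[ord])
}

#' Relation between two concepts in a possible world
#'
#' @param world An `euler_world`.
#' @param left,right Qualified concept ids.
#' @return A single relation keyword, or `NA` if either concept has an
#'   empty extension in this world (possible only when non-emptiness is
#'   toggled off).
#' @export
world_relation <- function(world, left, right) {
  stopifnot(inherits(world, "euler_world"))
  key <- paste(left, right, sep = "|")
  r <- unname(world$relations[key])
  if (is.na(r)) {
    r <- unname(world$relations[paste(right, left, sep = "|")])
    if (is.na(r)) stop("unknown concept pair: ", left, " / ", right,
                       call. = FALSE)
    if (startsWith(r, "void")) {
      r <- switch(r, void_left = "void_right", void_right = "void_left",
                  r)
    } else {
      r <- .rcc5_conv[[r]]
    }
  }
  if (startsWith(r, "void")) return(NA_character_)
  r
}

# constraint bundle shared by the solver and the oracle
.constraints <- function(problem, rs) {
  arts <- lapply(problem$articulations, function(a) {
    list(zones = .pair_zones(rs$inc, a$left, a$right),
         allowed = .zone_req[a$relation])
  })
  nonempty <- if (problem$toggles$non_emptiness) rs$inc else list()
  list(arts = arts, nonempty = nonempty)
}

# Depth-first search over region occupancy with constraint pruning.
# assign: logical vector with NA = undecided.  Each articulation prunes
# when no allowed zone triple remains realizable; each concept prunes when
# all its regions are decided empty (non-emptiness on).
.solve_worlds <- function(problem, cap = 1000L, first_only = FALSE) {
  diag <- validate_problem(problem)
  if (length(diag) > 0L) {
    stop("invalid alignment problem:\n  ", paste(diag, collapse = "\n  "),
         call. = FALSE)
  }
  rs <- .region_space(problem)
  n <- length(rs$regions)
  cons <- .constraints(problem, rs)
  pt <- .pair_table(rs)
  env <- new.env(parent = emptyenv())
  env$worlds <- list()
  env$keys <- character(0)
  env$overflow <- FALSE
  env$stop <- FALSE

  feasible <- function(assign) {
    for (a in cons$arts) {
      st <- lapply(a$zones, function(z) {
        v <- assign[z]
        c(occ = any(v, na.rm = TRUE), open = anyNA(v))
      })
      ok <- FALSE
      for (req in a$allowed) {
        good <- TRUE
        for (zi in 1:3) {
          s <- st[[zi]]
          if (req[zi]) {
            if (!s[["occ"]] && !s[["open"]]) { good <- FALSE; break }
          } else {
            if (s[["occ"]]) { good <- FALSE; break }
          }
        }
        if (good) { ok <- TRUE; break }
      }
      if (!ok) return(FALSE)
    }
    for (m in cons$nonempty) {
      v <- assign[m]
      if (!any(v, na.rm = TRUE) && !anyNA(v)) return(FALSE)
    }
    TRUE
  }

  recurse <- function(assign, pos) {
    if (env$stop) return(invisible())
    if (pos > n) {
      w <- .make_world(rs, which(assign), pt$names, pt$zones)
      if (!(w$key %in% env$keys)) {
        if (length(env$keys) >= cap) {
          env$overflow <- TRUE
          env$stop <- TRUE
          return(invisible())
        }
        env$keys <- c(env$keys, w$key)
        env$worlds[[length(env$worlds) + 1L]] <- w
        if (first_only) env$stop <- TRUE
      }
      return(invisible())
    }
    for (val in c(TRUE, FALSE)) {
      assign[pos] <- val
      if (feasible(assign)) recurse(assign, pos + 1L)
      if (env$stop) return(invisible())
    }
    invisible()
  }

  start <- rep(NA, n)
  if (n == 0L || feasible(start)) {
    if (n == 0L) {
      # degenerate: no regions at all (empty taxonomies)
    } else {
      recurse(start, 1L)
    }
  }
  ord <- order(vapply(env$worlds, `[[`, "", "key"))
  structure(env$worlds[ord], overflow = env$overflow)
}

#' Decide consistency of an alignment problem
#'
#' A problem is consistent iff at least one possible world satisfies the
#' taxonomies, all articulations, and the active constraints.
#'
#' @param problem An `euler_problem`.
#' @return Logical scalar; when `TRUE`, a witness world is attached as
#'   attribute `"witness"`.
#' @export
is_consistent <- function(problem) {
  res <- .solve_worlds(problem, cap = 1L, first_only = TRUE)
  if (length(res) > 0L) {
    structure(TRUE, witness = res[[1L]])
  } else {
    FALSE
  }
}

#' Enumerate all possible-world alignments
#'
#' Searches the candidate-region occupancy space depth-first with
#' constraint pruning and returns every distinct world, where world
#' identity is the induced assignment of one base relation to every
#' concept pair (within and across taxonomies).  Distinct occupancy
#' choices that induce the same relation assignment count as one world.
#'
#' @param problem An `euler_problem`.
#' @param cap Maximum number of distinct worlds to return (default 1000).
#'   If the cap is reached the attribute `"overflow"` on the result is
#'   `TRUE` and the result is truncated.
#' @return List of `euler_world` objects in a deterministic
#'   (lexicographic-by-relation-assignment) order, with attribute
#'   `"overflow"`.
#' @export
enumerate_worlds <- function(problem, cap = 1000L) {
  .solve_worlds(problem, cap = cap)
}

#' Brute-force world enumeration oracle
#'
#' Independent cross-check for [enumerate_worlds()] on small instances:
#' enumerates every subset of the candidate regions as the occupied set,
#' filters by non-emptiness and the articulation zone patterns, projects
#' each survivor to its pairwise relation assignment, and deduplicates.
#'
#' @param problem An `euler_problem` whose candidate-region count is at
#'   most 22.
#' @return List of `euler_world` objects, same identity and order
#'   convention as [enumerate_worlds()].
#' @export
oracle_worlds <- function(problem) {
  diag <- validate_problem(problem)
  if (length(diag) > 0L) {
    stop("invalid alignment problem:\n  ", paste(diag, collapse = "\n  "),
         call. = FALSE)
  }
  rs <- .region_space(problem)
  n <- length(rs$regions)
  if (n > 22L) {
    stop("instance too large for the brute-force oracle (", n,
         " candidate regions, limit 22)", call. = FALSE)
  }
  m <- 0:(2^n - 1L)
  bitmask <- function(idx) {
    if (length(idx) == 0L) 0L else sum(bitwShiftL(1L, idx - 1L))
  }
  keep <- rep(TRUE, length(m))
  if (problem$toggles$non_emptiness) {
    for (cm in rs$inc) keep <- keep & bitwAnd(m, bitmask(cm)) > 0L
  }
  for (a in problem$articulations) {
    z <- .pair_zones(rs$inc, a$left, a$right)
    l <- bitwAnd(m, bitmask(z$l)) > 0L
    s <- bitwAnd(m, bitmask(z$s)) > 0L
    r <- bitwAnd(m, bitmask(z$r)) > 0L
    rel <- .zone_lookup[4L * l + 2L * s + r + 1L]
    keep <- keep & rel %in% a$relation
  }
  ms <- m[keep]
  if (length(ms) == 0L) return(structure(list(), overflow = FALSE))
  pt <- .pair_table(rs)
  codes <- lapply(pt$zones, function(z) {
    l <- bitwAnd(ms, bitmask(z$l)) > 0L
    s <- bitwAnd(ms, bitmask(z$s)) > 0L
    r <- bitwAnd(ms, bitmask(z$r)) > 0L
    .zone_lookup[4L * l + 2L * s + r + 1L]
  })
  key <- do.call(paste, c(codes, sep = ","))
  first <- ms[!duplicated(key)]
  worlds <- lapply(first, function(mask) {
    occ <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) > 0L)
    .make_world(rs, occ, pt$names, pt$zones)
  })
  ord <- order(vapply(worlds, `[[`, "", "key"))
  structure(worlds[ord], overflow = FALSE)
}
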