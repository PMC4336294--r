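# Inconsistency diagnosis: minimal sets of input articulations whose
# removal restores consistency.

#' Repair options for an inconsistent alignment problem
#'
#' Enumerates every minimal correction set of articulations up to
#' `max_size`: a subset whose removal makes the problem consistent and no
#' proper subset of which does.  The search is breadth-first over subset
#' size with a consistency check per candidate, so supersets of an already
#' found option are never reported.  Only articulations are removal
#' candidates, never taxonomy edges or constraint toggles.
#'
#' @param problem An inconsistent `euler_problem`.
#' @param max_size Largest correction-set size to search (default 3;
#'   diagnosis degrades quickly when many erroneous articulations are
#'   present simultaneously, so larger searches must be requested
#'   explicitly).
#' @param cap World-enumeration cap used when counting the worlds of a
#'   repaired problem.
#' @return A list of repair options ordered by size then input order, each
#'   a list with `remove` (articulation indices), `articulations`, and
#'   `resulting_world_count`.  Attribute `"truncated"` is `TRUE` when no
#'   option was found within `max_size`.
#' @export
repair_options <- function(problem, max_size = 3L, cap = 1000L) {
  stopifnot(inherits(problem, "euler_problem"))
  if (isTRUE(as.logical(is_consistent(problem)))) {
    stop("the problem is consistent; nothing to repair", call. = FALSE)
  }
  n <- length(problem$articulations)
  found <- list()
  found_sets <- list()
  for (size in seq_len(min(max_size, n))) {
    combos <- utils::combn(n, size, simplify = FALSE)
    for (rm in combos) {
      if (any(vapply(found_sets, function(s) all(s %in% rm), logical(1)))) {
        next  # superset of a known minimal option
      }
      p2 <- problem
      p2$articulations <- problem$articulations[-rm]
      if (isTRUE(as.logical(is_consistent(p2)))) {
        wc <- length(enumerate_worlds(p2, cap = cap))
        found[[length(found) + 1L]] <-
          list(remove = rm,
               articulations = problem$articulations[rm],
               resulting_world_count = wc)
        found_sets[[length(found_sets) + 1L]] <- rm
      }
    }
  }
  structure(found, truncated = length(found) == 0L)
}
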