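# Maximally informative relations (MIR): the tightest relation set
# entailed for every ordered cross-taxonomy concept pair across all
# possible worlds, with provenance classification, minimal sufficient
# input search, and decision-tree question generation.

#' Compute maximally informative relations
#'
#' For every ordered cross-taxonomy pair (left concept from T2, right
#' concept from T1) collects the set of base relations the pair realizes
#' across the possible worlds.  A pair is resolved when a single relation
#' remains.
#'
#' @param problem An `euler_problem`.
#' @param worlds Non-empty list of `euler_world` objects, typically from
#'   [enumerate_worlds()].
#' @return Data frame of class `euler_mir` with columns `left`, `right`,
#'   `realized` (list of relation sets), `resolved`, and `provenance`
#'   (`NA` until [classify_mir()]).
#' @export
compute_mir <- function(problem, worlds) {
  stopifnot(inherits(problem, "euler_problem"))
  if (length(worlds) == 0L) {
    stop("empty world set: the problem is inconsistent, no MIR defined",
         call. = FALSE)
  }
  lefts <- .qualify(problem$t2, problem$t2$concepts)
  rights <- .qualify(problem$t1, problem$t1$concepts)
  grid <- expand.grid(right = rights, left = lefts,
                      stringsAsFactors = FALSE)[, c("left", "right")]
  realized <- lapply(seq_len(nrow(grid)), function(k) {
    rels <- vapply(worlds, world_relation, "", grid$left[k], grid$right[k])
    as_rcc5_set(unique(rels[!is.na(rels)]))
  })
  out <- data.frame(left = grid$left, right = grid$right,
                    stringsAsFactors = FALSE)
  out$realized <- realized
  out$resolved <- lengths(realized) == 1L
  out$provenance <- NA_character_
  class(out) <- c("euler_mir", "data.frame")
  out
}

#' Classify MIR entries as input, deduced, or inferred
#'
#' `input`: the pair appears in the input articulations with a singleton
#' relation.  `deduced`: a singleton relation for the pair is already
#' obtained by path-consistency closure ([rcc5_closure()]) over the input
#' articulations plus the taxonomy edges alone, each edge contributing
#' parent-includes-or-equals-child (no coverage reasoning).  `inferred`:
#' everything else, i.e. entries that require model-based reasoning over
#' the possible worlds.  Input entries are a subset of the deduced class;
#' summaries that report a deduced/inferred split count them as deduced.
#'
#' @param problem An `euler_problem`.
#' @param mir A MIR data frame from [compute_mir()].
#' @return The MIR data frame with `provenance` filled in.
#' @export
classify_mir <- function(problem, mir) {
  left <- character(0); right <- character(0); relation <- list()
  for (tax in list(problem$t1, problem$t2)) {
    if (nrow(tax$edges) > 0L) {
      left <- c(left, .qualify(tax, tax$edges$parent))
      right <- c(right, .qualify(tax, tax$edges$child))
      relation <- c(relation,
                    rep(list(c("equals", "includes")), nrow(tax$edges)))
    }
  }
  for (a in problem$articulations) {
    left <- c(left, a$left)
    right <- c(right, a$right)
    relation <- c(relation, list(a$relation))
  }
  cl <- rcc5_closure(left, right, relation,
                     concepts = .problem_concepts(problem))
  closed <- cl$relations
  ckey <- paste(closed$left, closed$right, sep = "|")
  input_pairs <- unlist(lapply(problem$articulations, function(a) {
    if (length(a$relation) == 1L) paste(a$left, a$right, sep = "|") else
      character(0)
  }))
  prov <- character(nrow(mir))
  for (k in seq_len(nrow(mir))) {
    pair <- paste(mir$left[k], mir$right[k], sep = "|")
    cset <- closed$relation[[match(pair, ckey)]]
    if (pair %in% input_pairs) {
      prov[k] <- "input"
    } else if (length(cset) == 1L) {
      prov[k] <- "deduced"
    } else {
      prov[k] <- "inferred"
    }
  }
  mir$provenance <- prov
  mir
}

#' Summary counts for a classified MIR table
#'
#' @param mir A classified MIR data frame.
#' @return Named integer vector with `deduced` (input entries included),
#'   `inferred`, and `total`.
#' @export
mir_summary <- function(mir) {
  ded <- sum(mir$provenance %in% c("input", "deduced"))
  inf <- sum(mir$provenance == "inferred")
  c(deduced = ded, inferred = inf, total = nrow(mir))
}

# world set signature: sorted keys
.world_signature <- function(worlds) {
  sort(vapply(worlds, `[[`, "", "key"))
}

#' Minimal sufficient subset of the input articulations
#'
#' Finds a subset of the input articulations that is minimal under
#' deletion and whose possible-world set (by relation-assignment
#' identity) equals that of the full input: greedy elimination in file
#' order, dropping each articulation whose removal leaves the world set
#' unchanged.
#'
#' @param problem A consistent `euler_problem` with a finite world set.
#' @param cap World-enumeration cap passed to [enumerate_worlds()].
#' @return Integer vector of retained articulation indices, with the
#'   retained articulations as attribute `"articulations"`.
#' @export
sufficient_subset <- function(problem, cap = 10000L) {
  target <- .world_signature(enumerate_worlds(problem, cap = cap))
  keep <- seq_along(problem$articulations)
  for (k in seq_along(problem$articulations)) {
    trial <- setdiff(keep, k)
    p2 <- problem
    p2$articulations <- problem$articulations[trial]
    if (identical(.world_signature(enumerate_worlds(p2, cap = cap)),
                  target)) {
      keep <- trial
    }
  }
  structure(keep, articulations = problem$articulations[keep])
}

#' Most informative disambiguation question
#'
#' When several possible worlds remain, the cross-taxonomy pair whose
#' realized relation set is largest is the question whose answer
#' maximally partitions the world set ("are these two concepts congruent
#' or are they overlapping?").  Ties break lexicographically by (left,
#' right).
#'
#' @param problem An `euler_problem`.
#' @param worlds Non-empty list of `euler_world` objects.
#' @return `NULL` if a single world remains; otherwise a list with
#'   `left`, `right`, and `relations` (the realized set).
#' @export
next_question <- function(problem, worlds) {
  stopifnot(length(worlds) > 0L)
  if (length(worlds) == 1L) return(NULL)
  mir <- compute_mir(problem, worlds)
  sz <- lengths(mir$realized)
  ord <- order(-sz, mir$left, mir$right)
  best <- ord[1L]
  list(left = mir$left[best], right = mir$right[best],
       relations = mir$realized[[best]])
}
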