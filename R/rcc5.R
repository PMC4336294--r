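# RCC-5 relation algebra: the five base relations between two non-empty
# sets, disjunction sets (the 32-element lattice), converse, composition,
# the zone-pattern characterization, and path-consistency closure.

#' The five RCC-5 base relations
#'
#' RCC-5 characterizes the relationship between the referential extensions
#' of two non-empty taxonomic concepts by exactly one of five base
#' relations: congruence (`equals`, glyph `==`), proper inclusion
#' (`includes`, `>`), inverse proper inclusion (`is_included_in`, `<`),
#' overlap (`overlaps`, `><`), and exclusion (`disjoint`, `|`).
#'
#' @return Character vector of the five relation keywords, in canonical
#'   order.
#' @seealso [rcc5_glyph()] for the display glyphs, [rcc5_relation_sets()]
#'   for the full disjunction lattice.
#' @export
#' @examples
#' rcc5_relations()
rcc5_relations <- function() .rcc5_base

.rcc5_base <- c("equals", "includes", "is_included_in", "overlaps",
                "disjoint")

.rcc5_glyphs <- c(equals = "==", includes = ">", is_included_in = "<",
                  overlaps = "><", disjoint = "|")

.rcc5_conv <- c(equals = "equals", includes = "is_included_in",
                is_included_in = "includes", overlaps = "overlaps",
                disjoint = "disjoint")

# Composition table over the base relations.  Each entry is the exact set
# of base relations realizable between A and C across all finite non-empty
# sets A, B, C with the first relation holding between A,B and the second
# between B,C.  Frozen from a brute-force enumeration over all triples of
# non-empty subsets of a 4-element universe; the test suite re-derives the
# table independently with the same enumeration.
.rcc5_comp <- list(
  "equals|equals" = c("equals"),
  "equals|includes" = c("includes"),
  "equals|is_included_in" = c("is_included_in"),
  "equals|overlaps" = c("overlaps"),
  "equals|disjoint" = c("disjoint"),
  "includes|equals" = c("includes"),
  "includes|includes" = c("includes"),
  "includes|is_included_in" = c("equals", "includes", "is_included_in",
                                "overlaps"),
  "includes|overlaps" = c("includes", "overlaps"),
  "includes|disjoint" = c("includes", "overlaps", "disjoint"),
  "is_included_in|equals" = c("is_included_in"),
  "is_included_in|includes" = c("equals", "includes", "is_included_in",
                                "overlaps", "disjoint"),
  "is_included_in|is_included_in" = c("is_included_in"),
  "is_included_in|overlaps" = c("is_included_in", "overlaps", "disjoint"),
  "is_included_in|disjoint" = c("disjoint"),
  "overlaps|equals" = c("overlaps"),
  "overlaps|includes" = c("includes", "overlaps", "disjoint"),
  "overlaps|is_included_in" = c("is_included_in", "overlaps"),
  "overlaps|overlaps" = c("equals", "includes", "is_included_in",
                          "overlaps", "disjoint"),
  "overlaps|disjoint" = c("includes", "overlaps", "disjoint"),
  "disjoint|equals" = c("disjoint"),
  "disjoint|includes" = c("disjoint"),
  "disjoint|is_included_in" = c("is_included_in", "overlaps", "disjoint"),
  "disjoint|overlaps" = c("is_included_in", "overlaps", "disjoint"),
  "disjoint|disjoint" = c("equals", "includes", "is_included_in",
                          "overlaps", "disjoint")
)

#' Display glyphs for RCC-5 relations
#'
#' @param r Character vector of relation keywords.
#' @return Character vector of glyphs (`==`, `>`, `<`, `><`, `|`).
#' @export
#' @examples
#' rcc5_glyph(c("overlaps", "disjoint"))
rcc5_glyph <- function(r) {
  unname(.rcc5_glyphs[as_rcc5_set(r)])
}

#' Canonicalize an RCC-5 relation set
#'
#' Validates the keywords and returns them deduplicated in canonical order.
#' The empty set is representable (it is the inconsistency signal of
#' [rcc5_closure()]) but is not legal as a user-supplied articulation.
#'
#' @param x Character vector of relation keywords (possibly empty), or a
#'   single string such as `"{includes overlaps}"`.
#' @return Character vector, a canonical subset of [rcc5_relations()].
#' @export
#' @examples
#' as_rcc5_set(c("overlaps", "equals", "equals"))
as_rcc5_set <- function(x) {
  if (length(x) == 1L && grepl("[{} ]", x)) {
    x <- strsplit(gsub("[{}]", "", x), "[[:space:]]+")[[1]]
    x <- x[nzchar(x)]
  }
  bad <- setdiff(x, .rcc5_base)
  if (length(bad) > 0L) {
    stop("unknown RCC-5 relation keyword(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  .rcc5_base[.rcc5_base %in% x]
}

# compact string form: single keyword, or brace-wrapped space-separated set
.rcc5_set_string <- function(x) {
  x <- as_rcc5_set(x)
  if (length(x) == 0L) "{}" else if (length(x) == 1L) x else
    paste0("{", paste(x, collapse = " "), "}")
}

#' All 32 RCC-5 relation sets
#'
#' Disjunctions of the five base relations form a lattice of 32 possible
#' articulations, from the empty set up to the maximally ambiguous
#' five-member set.
#'
#' @return List of 32 character vectors in a fixed order (empty set first).
#' @export
#' @examples
#' length(rcc5_relation_sets())
rcc5_relation_sets <- function() {
  lapply(0:31, function(m) .rcc5_base[bitwAnd(m, bitwShiftL(1L, 0:4)) > 0L])
}

#' Converse of an RCC-5 relation set
#'
#' Member-wise converse: `equals`, `overlaps` and `disjoint` are
#' self-converse; `includes` and `is_included_in` swap.  Involutive.
#'
#' @param r Character vector of relation keywords (possibly empty).
#' @return The converse set, canonically ordered.
#' @export
#' @examples
#' rcc5_converse(c("includes", "overlaps"))
rcc5_converse <- function(r) {
  r <- as_rcc5_set(r)
  .rcc5_base[.rcc5_base %in% unname(.rcc5_conv[r])]
}

#' Composition of RCC-5 relations
#'
#' For relation sets `r1` (between A and B) and `r2` (between B and C),
#' returns the set of base relations realizable between A and C, i.e. the
#' union over all pairs of members of the base-relation composition table.
#'
#' @param r1,r2 Character vectors of relation keywords.
#' @return Character vector, the composed relation set.
#' @export
#' @examples
#' rcc5_compose("includes", "disjoint")
#' rcc5_compose("overlaps", "overlaps")
rcc5_compose <- function(r1, r2) {
  r1 <- as_rcc5_set(r1)
  r2 <- as_rcc5_set(r2)
  out <- character(0)
  for (a in r1) for (b in r2) {
    out <- union(out, .rcc5_comp[[paste(a, b, sep = "|")]])
  }
  .rcc5_base[.rcc5_base %in% out]
}

#' RCC-5 relation from the emptiness pattern of the three zones
#'
#' Two non-empty concepts A and B partition their joint extension into
#' three zones: unique-to-A (A\\B), shared (A*B), and unique-to-B (B\\A).
#' The emptiness status of the zones determines the base relation:
#' only-shared is congruence, a missing unique zone gives a proper
#' inclusion, all three occupied is overlap, and an empty shared zone with
#' both unique zones occupied is exclusion.
#'
#' @param left_only,shared,right_only Logicals: is the corresponding zone
#'   non-empty?
#' @return A single relation keyword.
#' @export
#' @examples
#' relation_from_zones(TRUE, TRUE, TRUE)   # overlaps
#' relation_from_zones(FALSE, TRUE, FALSE) # equals
relation_from_zones <- function(left_only, shared, right_only) {
  stopifnot(is.logical(left_only), is.logical(shared),
            is.logical(right_only))
  if (!left_only && !shared) {
    stop("invalid zone pattern: left concept has empty extension ",
         "(non-emptiness violated)", call. = FALSE)
  }
  if (!right_only && !shared) {
    stop("invalid zone pattern: right concept has empty extension ",
         "(non-emptiness violated)", call. = FALSE)
  }
  .zone_code(left_only, shared, right_only)
}

# Unchecked zone lookup; returns NA-like sentinels for empty concepts so
# the reasoner can key worlds even when non-emptiness is toggled off.
.zone_code <- function(l, s, r) {
  if (!s) {
    if (!l && !r) return("void_both")
    if (!l) return("void_left")
    if (!r) return("void_right")
    return("disjoint")
  }
  if (l && r) return("overlaps")
  if (l) return("includes")
  if (r) return("is_included_in")
  "equals"
}

# zone requirements (left_only, shared, right_only) per base relation
.zone_req <- list(
  equals         = c(FALSE, TRUE, FALSE),
  includes       = c(TRUE, TRUE, FALSE),
  is_included_in = c(FALSE, TRUE, TRUE),
  overlaps       = c(TRUE, TRUE, TRUE),
  disjoint       = c(TRUE, FALSE, TRUE)
)

# ---- bitmask helpers for the closure --------------------------------------

.rcc5_bit <- stats::setNames(bitwShiftL(1L, 0:4), .rcc5_base)

.mask_of <- function(r) {
  if (length(r) == 0L) return(0L)
  sum(.rcc5_bit[r])
}

.set_of <- function(mask) .rcc5_base[bitwAnd(mask, .rcc5_bit) > 0L]

.conv_mask_tab <- vapply(0:31, function(m) {
  .mask_of(unname(.rcc5_conv[.set_of(m)]))
}, integer(1))

.comp_mask_tab <- local({
  tab <- matrix(0L, 5L, 5L, dimnames = list(.rcc5_base, .rcc5_base))
  for (a in .rcc5_base) for (b in .rcc5_base) {
    tab[a, b] <- .mask_of(.rcc5_comp[[paste(a, b, sep = "|")]])
  }
  tab
})

.compose_mask <- function(m1, m2) {
  out <- 0L
  for (i in seq_len(5L)) {
    if (bitwAnd(m1, bitwShiftL(1L, i - 1L)) == 0L) next
    for (j in seq_len(5L)) {
      if (bitwAnd(m2, bitwShiftL(1L, j - 1L)) > 0L) {
        out <- bitwOr(out, .comp_mask_tab[i, j])
      }
    }
  }
  out
}

#' Path-consistency closure of an RCC-5 constraint network
#'
#' Takes a network of RCC-5 constraints over named concepts and repeatedly
#' refines every pair (a, c) by intersecting its relation set with the
#' union of compositions through every intermediate b, until a fixpoint.
#' The result is member-wise contained in the input.  An empty relation
#' set arising at any pair signals that the network is inconsistent (for
#' example, two concepts asserted to properly include each other).
#'
#' @param left,right Character vectors of concept names (parallel).
#' @param relation List of relation-set character vectors (parallel to
#'   `left`), or a character vector of set strings such as
#'   `"{includes overlaps}"`.
#' @param concepts Optional character vector fixing the node set and its
#'   order; defaults to the concepts appearing in `left`/`right`.
#' @return A list with elements `consistent` (logical), `concepts`, and
#'   `relations`: a data frame of all ordered pairs with a `relation`
#'   list-column holding the closed sets.
#' @export
#' @examples
#' cl <- rcc5_closure(c("A", "B"), c("B", "C"),
#'                    list("equals", "includes"))
#' cl$relations$relation[[which(cl$relations$left == "A" &
#'                              cl$relations$right == "C")]]
rcc5_closure <- function(left, right, relation, concepts = NULL) {
  stopifnot(length(left) == length(right))
  if (is.character(relation)) relation <- as.list(relation)
  stopifnot(length(relation) == length(left))
  relation <- lapply(relation, as_rcc5_set)
  if (is.null(concepts)) concepts <- unique(c(rbind(left, right)))
  n <- length(concepts)
  idx <- stats::setNames(seq_len(n), concepts)
  full <- 31L
  R <- matrix(full, n, n)
  diag(R) <- .rcc5_bit[["equals"]]
  for (k in seq_along(left)) {
    i <- idx[[left[k]]]
    j <- idx[[right[k]]]
    m <- .mask_of(relation[[k]])
    R[i, j] <- bitwAnd(R[i, j], m)
    R[j, i] <- bitwAnd(R[j, i], .conv_mask_tab[m + 1L])
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        if (R[i, k] == 0L || R[k, j] == 0L) next
        m <- bitwAnd(R[i, j], .compose_mask(R[i, k], R[k, j]))
        if (m != R[i, j]) {
          R[i, j] <- m
          R[j, i] <- .conv_mask_tab[m + 1L]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  pairs <- expand.grid(right = concepts, left = concepts,
                       stringsAsFactors = FALSE)[, c("left", "right")]
  pairs <- pairs[pairs$left != pairs$right, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs$relation <- lapply(seq_len(nrow(pairs)), function(r) {
    .set_of(R[idx[[pairs$left[r]]], idx[[pairs$right[r]]]])
  })
  list(consistent = all(R[row(R) != col(R)] != 0L) || n < 2L,
       concepts = concepts, relations = pairs)
}
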