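# Domain model: taxonomies (rooted trees of concepts), articulations, and
# the full alignment problem (two taxonomies + articulations + constraint
# toggles).

#' Construct a taxonomy
#'
#' A taxonomy is a single-rooted tree of taxonomic concepts connected by
#' parent-child (`is_a`) edges.  Edges carry subset semantics: a child's
#' extension is contained in (not necessarily properly contained in) its
#' parent's.  Under the coverage constraint a parent's extension is the
#' union of its children's; coverage can be switched off per parent
#' ("nc", non-coverage), in which case the parent may extend beyond its
#' listed children.
#'
#' @param id Short taxonomy identifier, e.g. `"1954"`; used as the prefix
#'   of qualified concept ids (`"1954.PER"`).
#' @param edges Data frame with columns `parent` and `child` (bare concept
#'   labels), or a named list mapping each parent label to a character
#'   vector of child labels.
#' @param display_name Human-readable name; defaults to `id`.
#' @param coverage_off Character vector of parent labels for which the
#'   coverage constraint is relaxed.
#' @param implied Character vector of labels flagged as user-introduced
#'   implied children ("IC" concepts); annotation only, no special
#'   semantics.  Defaults to labels ending in `"_IC"`.
#' @param concepts Optional explicit concept list (bare labels); must
#'   contain every label appearing in `edges`.  Needed for isolated
#'   concepts, e.g. a single-concept taxonomy with no edges.
#' @return An object of class `euler_taxonomy`.
#' @export
#' @examples
#' taxonomy("1954", list(PER = c("Pcarlud", "Prectir", "Psubcin")))
taxonomy <- function(id, edges, display_name = id,
                     coverage_off = character(), implied = NULL,
                     concepts = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- if (length(edges) == 0L) {
      data.frame(parent = character(0), child = character(0),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(
        parent = rep(names(edges), lengths(edges)),
        child = unlist(edges, use.names = FALSE),
        stringsAsFactors = FALSE
      )
    }
  }
  stopifnot(is.data.frame(edges), all(c("parent", "child") %in% names(edges)))
  edges <- data.frame(parent = as.character(edges$parent),
                      child = as.character(edges$child),
                      stringsAsFactors = FALSE)
  derived <- unique(c(rbind(edges$parent, edges$child)))
  if (nrow(edges) == 0L) derived <- character(0)
  if (is.null(concepts)) {
    concepts <- derived
  } else {
    stopifnot(all(derived %in% concepts))
  }
  if (is.null(implied)) implied <- grep("_IC$", concepts, value = TRUE)
  structure(
    list(id = id, display_name = display_name, concepts = concepts,
         edges = edges, coverage_off = unique(coverage_off),
         implied = implied),
    class = "euler_taxonomy"
  )
}

# single-concept taxonomy (no edges)
taxonomy1 <- function(id, label, display_name = id) {
  taxonomy(id, data.frame(parent = character(0), child = character(0)),
           display_name = display_name, concepts = label)
}

#' @export
print.euler_taxonomy <- function(x, ...) {
  cat(sprintf("Taxonomy %s (%s): %d concepts, %d edges\n", x$id,
              x$display_name, length(x$concepts), nrow(x$edges)))
  if (length(x$coverage_off) > 0L) {
    cat("  non-coverage parents:", paste(x$coverage_off, collapse = ", "),
        "\n")
  }
  invisible(x)
}

.qualify <- function(tax, labels) {
  if (length(labels) == 0L) return(character(0))
  paste(tax$id, labels, sep = ".")
}

.tax_children <- function(tax) {
  split(tax$edges$child, factor(tax$edges$parent, levels = tax$concepts))
}

.tax_parent <- function(tax) {
  stats::setNames(tax$edges$parent, tax$edges$child)
}

.tax_root <- function(tax) {
  setdiff(tax$concepts, tax$edges$child)
}

# self + ancestors, in leaf-to-root order
.tax_chain <- function(tax, label) {
  parent <- .tax_parent(tax)
  out <- label
  while (label %in% names(parent)) {
    label <- parent[[label]]
    out <- c(out, label)
  }
  out
}

#' Leaf concepts of a taxonomy
#'
#' @param tax An `euler_taxonomy`.
#' @param qualified Return qualified ids (`"1954.Pcarlud"`) rather than
#'   bare labels?
#' @return Character vector of concepts without children.
#' @export
#' @examples
#' taxonomy_leaves(taxonomy("1954", list(PER = c("Pcarlud", "Prectir"))))
taxonomy_leaves <- function(tax, qualified = TRUE) {
  stopifnot(inherits(tax, "euler_taxonomy"))
  leaves <- setdiff(tax$concepts, tax$edges$parent)
  if (qualified) .qualify(tax, leaves) else leaves
}

#' Construct an articulation
#'
#' An articulation is an RCC-5 statement (possibly a disjunction) relating
#' the extensions of two concepts from different taxonomies.  By
#' convention the left concept comes from the more recently published
#' taxonomy (T2) and the right concept from the earlier one (T1).
#'
#' @param left,right Qualified concept ids, e.g. `"1954.PER"`.
#' @param relation Character vector of relation keywords (a non-empty
#'   subset of [rcc5_relations()]), or a set string such as
#'   `"{includes overlaps}"`.
#' @param tag Optional reading annotation (`"OST"`, `"INT"`,
#'   `"INT/OST"`); carried as metadata only and never used in reasoning.
#' @return An object of class `euler_articulation`.
#' @export
#' @examples
#' articulation("1954.Pcarlud", "equals", "1936.ELLcarlud")
articulation <- function(left, relation, right, tag = NA_character_) {
  relation <- as_rcc5_set(relation)
  if (length(relation) == 0L) {
    stop("an articulation's relation set must be non-empty", call. = FALSE)
  }
  structure(list(left = left, relation = relation, right = right,
                 tag = tag),
            class = "euler_articulation")
}

#' @export
print.euler_articulation <- function(x, ...) {
  cat(sprintf("[%s %s %s]%s\n", x$left, .rcc5_set_string(x$relation),
              x$right,
              if (is.na(x$tag)) "" else paste0("  # ", x$tag)))
  invisible(x)
}

#' Construct an alignment problem
#'
#' Bundles the two input taxonomies, the expert articulations, and the
#' global constraint toggles.  `t1` is the earlier taxonomy and `t2` the
#' more recent one; articulations are stated with the `t2` concept on the
#' left.
#'
#' @param t1,t2 `euler_taxonomy` objects with distinct ids.
#' @param articulations List of [articulation()] objects.
#' @param non_emptiness Require every concept to have at least one
#'   instance?  Default `TRUE`.
#' @param sibling_disjointness Require children of one parent to have
#'   mutually exclusive extensions?  Default `TRUE`.
#' @param coverage Enforce coverage globally (except for parents flagged
#'   non-coverage)?  Default `TRUE`.
#' @return An object of class `euler_problem`.
#' @export
alignment_problem <- function(t1, t2, articulations = list(),
                              non_emptiness = TRUE,
                              sibling_disjointness = TRUE,
                              coverage = TRUE) {
  stopifnot(inherits(t1, "euler_taxonomy"), inherits(t2, "euler_taxonomy"))
  if (inherits(articulations, "euler_articulation")) {
    articulations <- list(articulations)
  }
  structure(
    list(t1 = t1, t2 = t2, articulations = articulations,
         toggles = list(non_emptiness = non_emptiness,
                        sibling_disjointness = sibling_disjointness,
                        coverage = coverage)),
    class = "euler_problem"
  )
}

#' @export
print.euler_problem <- function(x, ...) {
  cat(sprintf("Alignment problem: T1 = %s (%d concepts), T2 = %s (%d concepts), %d articulations\n",
              x$t1$id, length(x$t1$concepts), x$t2$id,
              length(x$t2$concepts), length(x$articulations)))
  off <- names(Filter(isFALSE, x$toggles))
  if (length(off) > 0L) cat("  toggled off:", paste(off, collapse = ", "), "\n")
  invisible(x)
}

# all qualified concept ids, T1 first, in document order
.problem_concepts <- function(problem) {
  c(.qualify(problem$t1, problem$t1$concepts),
    .qualify(problem$t2, problem$t2$concepts))
}

#' Validate an alignment problem
#'
#' Structural validation: reports (rather than throws) every violation
#' found, so that a problem can be fully diagnosed in one pass.  Checks
#' include duplicate taxonomy ids, malformed labels, tree violations
#' (multiple parents, multiple roots, cycles), non-coverage flags on
#' non-parents, dangling articulation endpoints, same-taxonomy
#' articulations, and empty relation sets.
#'
#' @param problem An `euler_problem`.
#' @return Character vector of diagnostics; empty iff structurally valid.
#' @export
validate_problem <- function(problem) {
  stopifnot(inherits(problem, "euler_problem"))
  out <- character(0)
  if (problem$t1$id == problem$t2$id) {
    out <- c(out, sprintf("duplicate taxonomy id '%s'", problem$t1$id))
  }
  for (tax in list(problem$t1, problem$t2)) {
    bad <- grep("^[A-Za-z0-9_]+$", tax$concepts, value = TRUE,
                invert = TRUE)
    for (b in bad) {
      out <- c(out, sprintf("taxonomy %s: label '%s' violates the token grammar",
                            tax$id, b))
    }
    dup <- unique(tax$edges$child[duplicated(tax$edges$child)])
    for (d in dup) {
      out <- c(out, sprintf("taxonomy %s: concept '%s' listed under two parents",
                            tax$id, d))
    }
    if (length(tax$concepts) > 0L && length(dup) == 0L) {
      roots <- .tax_root(tax)
      if (length(roots) != 1L) {
        out <- c(out, sprintf("taxonomy %s: expected a single root, found %d (%s)",
                              tax$id, length(roots),
                              paste(roots, collapse = ", ")))
      } else {
        # reachability from the root catches cycles / disconnected parts
        seen <- roots
        frontier <- roots
        ch <- .tax_children(tax)
        while (length(frontier) > 0L) {
          nxt <- setdiff(unlist(ch[frontier], use.names = FALSE), seen)
          seen <- c(seen, nxt)
          frontier <- nxt
        }
        orphan <- setdiff(tax$concepts, seen)
        if (length(orphan) > 0L) {
          out <- c(out, sprintf("taxonomy %s: concepts unreachable from root (cycle or disconnect): %s",
                                tax$id, paste(orphan, collapse = ", ")))
        }
      }
    }
    stray <- setdiff(tax$coverage_off, tax$edges$parent)
    for (s in stray) {
      out <- c(out, sprintf("taxonomy %s: non-coverage flag on '%s', which has no children",
                            tax$id, s))
    }
  }
  known <- .problem_concepts(problem)
  tids <- c(problem$t1$id, problem$t2$id)
  for (k in seq_along(problem$articulations)) {
    a <- problem$articulations[[k]]
    for (side in c("left", "right")) {
      if (!a[[side]] %in% known) {
        out <- c(out, sprintf("articulation %d: dangling concept reference '%s'",
                              k, a[[side]]))
      }
    }
    tl <- sub("\\..*$", "", a$left)
    tr <- sub("\\..*$", "", a$right)
    if (tl == tr && all(c(a$left, a$right) %in% known)) {
      out <- c(out, sprintf("articulation %d: both concepts from taxonomy '%s'",
                            k, tl))
    }
    if (length(a$relation) == 0L) {
      out <- c(out, sprintf("articulation %d: empty relation set", k))
    }
  }
  out
}
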