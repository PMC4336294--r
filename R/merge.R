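# Merge visual products of a single possible world: congruence clusters,
# the containment-with-overlap graph, and the merge-concept (Euler region)
# graph.

# occupied-region extension of a concept: indices of world regions whose
# membership contains it
.world_extension <- function(world, qid) {
  which(vapply(world$regions, function(r) qid %in% r, logical(1)))
}

.taxonomy_of <- function(qid) sub("\\..*$", "", qid)

#' Congruence clusters of a possible world
#'
#' Partitions all concepts (both taxonomies) into equivalence classes
#' under the world's congruence (`equals`) relation.  A cluster's
#' provenance is `both` iff it contains concepts from both taxonomies.
#'
#' @param world An `euler_world`.
#' @param t1_id,t2_id Taxonomy ids used for provenance; by default taken
#'   from the concepts' qualified-id prefixes in document order.
#' @return List of clusters: each a list with `members` (qualified ids,
#'   T2 members first), `provenance` (`both`, `T1_only`, `T2_only`), and
#'   `label`.
#' @export
congruence_clusters <- function(world, t1_id = NULL, t2_id = NULL) {
  stopifnot(inherits(world, "euler_world"))
  qq <- world$concepts
  if (is.null(t1_id)) t1_id <- .taxonomy_of(qq[1])
  if (is.null(t2_id)) t2_id <- .taxonomy_of(qq[length(qq)])
  n <- length(qq)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- world_relation(world, qq[i], qq[j])
    if (identical(r, "equals")) {
      comp[find(j)] <- find(i)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- list()
  for (r in unique(roots)) {
    members <- qq[roots == r]
    taxa <- .taxonomy_of(members)
    prov <- if (all(taxa == t1_id)) "T1_only" else
      if (all(taxa == t2_id)) "T2_only" else "both"
    members <- c(members[taxa == t2_id], members[taxa != t2_id])
    out[[length(out) + 1L]] <-
      list(members = members, provenance = prov,
           label = paste(members, collapse = "+"))
  }
  out
}

.new_merge_graph <- function(nodes, inclusion, overlap) {
  structure(list(nodes = nodes, inclusion = inclusion, overlap = overlap),
            class = "merge_graph")
}

#' @export
print.merge_graph <- function(x, ...) {
  cat(sprintf("Merge graph: %d nodes, %d inclusion edges, %d overlap edges\n",
              length(x$nodes), nrow(x$inclusion), nrow(x$overlap)))
  invisible(x)
}

# transitive reduction of an acyclic edge set given as from/to id vectors
.transitive_reduction <- function(from, to) {
  if (length(from) == 0L) {
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  }
  keep <- rep(TRUE, length(from))
  # an edge is redundant if its head is reachable without it
  for (k in seq_along(from)) {
    adj_from <- from[-k]
    adj_to <- to[-k]
    frontier <- adj_to[adj_from == from[k]]
    seen <- character(0)
    while (length(frontier) > 0L) {
      seen <- union(seen, frontier)
      frontier <- setdiff(adj_to[adj_from %in% frontier], seen)
    }
    if (to[k] %in% seen) keep[k] <- FALSE
  }
  data.frame(from = from[keep], to = to[keep], stringsAsFactors = FALSE)
}

#' Containment-with-overlap graph of a possible world
#'
#' Nodes are the congruence clusters; directed inclusion edges are the
#' transitive reduction of the world's proper-inclusion order on
#' clusters; undirected overlap edges connect cluster pairs whose world
#' relation is `overlaps`.
#'
#' @param problem The `euler_problem` the world came from.
#' @param world An `euler_world`.
#' @return A `merge_graph` with cluster nodes.
#' @export
containment_graph <- function(problem, world) {
  clusters <- congruence_clusters(world, problem$t1$id, problem$t2$id)
  nodes <- lapply(clusters, function(cl) {
    list(id = cl$label, kind = "cluster", members = cl$members,
         provenance = cl$provenance, labels = cl$label,
         extension = .world_extension(world, cl$members[1]))
  })
  nc <- length(nodes)
  from <- character(0); to <- character(0)
  oa <- character(0); ob <- character(0)
  for (i in seq_len(nc)) for (j in seq_len(nc)) {
    if (i == j) next
    r <- world_relation(world, nodes[[i]]$members[1], nodes[[j]]$members[1])
    if (identical(r, "includes")) {
      from <- c(from, nodes[[i]]$id)
      to <- c(to, nodes[[j]]$id)
    } else if (identical(r, "overlaps") && i < j) {
      oa <- c(oa, nodes[[i]]$id)
      ob <- c(ob, nodes[[j]]$id)
    }
  }
  .new_merge_graph(nodes, .transitive_reduction(from, to),
                   data.frame(a = oa, b = ob, stringsAsFactors = FALSE))
}

#' Merge-concept (Euler region) graph of a possible world
#'
#' Starts from the congruence clusters and resolves every overlapping
#' cluster pair (A, B) into its occupied Euler regions: unique-to-A
#' (labelled `A\B`), shared (`A*B`, operands in lexicographic order), and
#' unique-to-B (`B\A`).  A region whose extension coincides with an
#' existing node is not duplicated; the region label is attached to that
#' node as an alias.  Inclusion edges are rebuilt from proper containment
#' of node extensions and transitively reduced; resolved overlaps carry no
#' overlap edge.
#'
#' @param problem The `euler_problem` the world came from.
#' @param world An `euler_world`.
#' @return A `merge_graph` whose nodes are clusters and Euler regions.
#' @export
merge_concept_graph <- function(problem, world) {
  base <- containment_graph(problem, world)
  nodes <- base$nodes
  ext_key <- function(e) paste(sort(e), collapse = ",")
  keys <- vapply(nodes, function(nd) ext_key(nd$extension), "")
  region_prov <- function(ext) {
    taxa <- unique(.taxonomy_of(unlist(world$regions[ext],
                                       use.names = FALSE)))
    if (length(taxa) > 1L) "both" else
      if (taxa == problem$t1$id) "T1_only" else "T2_only"
  }
  add_region <- function(label, ext) {
    if (length(ext) == 0L) return(invisible())
    k <- ext_key(ext)
    hit <- match(k, keys)
    if (!is.na(hit)) {
      nodes[[hit]]$labels <<- union(nodes[[hit]]$labels, label)
    } else {
      nodes[[length(nodes) + 1L]] <<-
        list(id = label, kind = "euler_region", members = character(0),
             provenance = region_prov(ext), labels = label,
             extension = ext)
      keys <<- c(keys, k)
    }
  }
  ov <- base$overlap
  for (k in seq_len(nrow(ov))) {
    i <- match(ov$a[k], vapply(nodes, `[[`, "", "id"))
    j <- match(ov$b[k], vapply(nodes, `[[`, "", "id"))
    A <- nodes[[i]]; B <- nodes[[j]]
    ops <- sort(c(A$id, B$id))
    add_region(paste0(A$id, "\\", B$id), setdiff(A$extension, B$extension))
    add_region(paste0(ops[1], "*", ops[2]),
               intersect(A$extension, B$extension))
    add_region(paste0(B$id, "\\", A$id), setdiff(B$extension, A$extension))
  }
  n <- length(nodes)
  from <- character(0); to <- character(0)
  oa <- character(0); ob <- character(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ei <- nodes[[i]]$extension
    ej <- nodes[[j]]$extension
    if (all(ej %in% ei) && !all(ei %in% ej)) {
      from <- c(from, nodes[[i]]$id)
      to <- c(to, nodes[[j]]$id)
    } else if (i < j && length(intersect(ei, ej)) > 0L &&
               !all(ei %in% ej) && !all(ej %in% ei)) {
      # partial overlap: unresolved only if no node carries the shared part
      if (!(ext_key(intersect(ei, ej)) %in% keys)) {
        oa <- c(oa, nodes[[i]]$id)
        ob <- c(ob, nodes[[j]]$id)
      }
    }
  }
  .new_merge_graph(nodes, .transitive_reduction(from, to),
                   data.frame(a = oa, b = ob, stringsAsFactors = FALSE))
}
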