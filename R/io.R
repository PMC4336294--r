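# Plain-text problem format, MIR tables, and DOT graph output.
#
# Problem file grammar (blank line between blocks, "#" comments anywhere):
#
#   taxonomy <id> <display_name>
#   (<parent> <child> <child> ... [nc])
#   ...
#
#   taxonomy <id> <display_name>
#   ...
#
#   articulation <name>
#   [<tax.concept> <relation> <tax.concept>]
#   [<tax.concept> {<relation> <relation> ...} <tax.concept>]
#
# Concept references inside taxonomy blocks are bare labels (the taxonomy
# prefix is implicit); inside the articulation block they are fully
# qualified ("1954.PER").

#' Parse an alignment problem from its text format
#'
#' @param text Character scalar (the whole document) or vector of lines.
#' @param file Path to a problem file (alternative to `text`).
#' @return An `euler_problem`.  Comment lines are preserved in attribute
#'   `"comments"`; the articulation block name in attribute `"name"`.
#' @export
parse_problem <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(file))
    text <- readLines(file, warn = FALSE)
  }
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  comments <- grep("^[[:space:]]*#", text, value = TRUE)
  taxa <- list()
  arts <- list()
  art_name <- NA_character_
  current <- NULL   # taxonomy under construction
  in_art <- FALSE
  perr <- function(i, msg) {
    stop(sprintf("parse error at line %d: %s (%s)", i, msg,
                 trimws(text[i])), call. = FALSE)
  }
  flush_tax <- function() {
    if (!is.null(current)) {
      tx <- taxonomy(current$id,
                     data.frame(parent = current$parent,
                                child = current$child,
                                stringsAsFactors = FALSE),
                     display_name = current$name,
                     coverage_off = current$nc)
      if (length(tx$concepts) == 0L && length(current$solo) > 0L) {
        tx$concepts <- current$solo
      }
      taxa[[length(taxa) + 1L]] <<- tx
      current <<- NULL
    }
  }
  for (i in seq_along(text)) {
    line <- trimws(text[i])
    if (line == "" || startsWith(line, "#")) next
    if (grepl("^taxonomy\\b", line)) {
      flush_tax()
      tok <- strsplit(line, "[[:space:]]+")[[1]]
      if (length(tok) < 2L) perr(i, "taxonomy line needs an id")
      if (any(vapply(taxa, function(t) t$id == tok[2], logical(1)))) {
        perr(i, paste0("duplicate taxonomy id '", tok[2], "'"))
      }
      current <- list(id = tok[2],
                      name = if (length(tok) >= 3L) tok[3] else tok[2],
                      parent = character(0), child = character(0),
                      nc = character(0), solo = character(0))
      in_art <- FALSE
    } else if (grepl("^articulation\\b", line)) {
      flush_tax()
      tok <- strsplit(line, "[[:space:]]+")[[1]]
      art_name <- if (length(tok) >= 2L) tok[2] else NA_character_
      in_art <- TRUE
    } else if (grepl("^\\(.*\\)$", line)) {
      if (is.null(current)) perr(i, "parent-child line outside a taxonomy block")
      tok <- strsplit(trimws(gsub("[()]", "", line)), "[[:space:]]+")[[1]]
      nc <- FALSE
      if (length(tok) > 1L && tok[length(tok)] == "nc") {
        nc <- TRUE
        tok <- tok[-length(tok)]
      }
      if (length(tok) < 1L) perr(i, "empty parent-child line")
      if (length(tok) == 1L) {
        current$solo <- c(current$solo, tok[1])
      } else {
        current$parent <- c(current$parent, rep(tok[1], length(tok) - 1L))
        current$child <- c(current$child, tok[-1])
      }
      if (nc) current$nc <- c(current$nc, tok[1])
    } else if (grepl("^\\[.*\\]$", line)) {
      if (!in_art) perr(i, "articulation outside an articulation block")
      body <- trimws(sub("^\\[", "", sub("\\]$", "", line)))
      m <- regmatches(body,
                      regexec("^([^[:space:]]+)[[:space:]]+(\\{[^}]*\\}|[^[:space:]]+)[[:space:]]+([^[:space:]]+)$",
                              body))[[1]]
      if (length(m) != 4L) perr(i, "malformed articulation")
      rel <- tryCatch(as_rcc5_set(m[3]), error = function(e) {
        perr(i, conditionMessage(e))
      })
      if (length(rel) == 0L) perr(i, "empty relation set")
      arts[[length(arts) + 1L]] <- articulation(m[2], rel, m[4])
    } else {
      perr(i, "unrecognized line")
    }
  }
  flush_tax()
  if (length(taxa) != 2L) {
    stop(sprintf("expected exactly 2 taxonomy blocks, found %d",
                 length(taxa)), call. = FALSE)
  }
  problem <- alignment_problem(taxa[[1]], taxa[[2]], arts)
  known <- .problem_concepts(problem)
  for (k in seq_along(arts)) {
    a <- arts[[k]]
    miss <- setdiff(c(a$left, a$right), known)
    if (length(miss) > 0L) {
      stop("dangling concept reference in articulation ", k, ": ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  attr(problem, "comments") <- comments
  attr(problem, "name") <- art_name
  problem
}

#' Render an alignment problem to its canonical text format
#'
#' Inverse of [parse_problem()] up to ordering: `parse_problem(render_problem(p))`
#' yields an equivalent problem.
#'
#' @param problem An `euler_problem`.
#' @param name Articulation block name (default `"alignment"`).
#' @return Character scalar, the document text.
#' @export
render_problem <- function(problem, name = "alignment") {
  stopifnot(inherits(problem, "euler_problem"))
  render_tax <- function(tax) {
    out <- sprintf("taxonomy %s %s", tax$id, tax$display_name)
    ch <- .tax_children(tax)
    for (p in tax$concepts) {
      kids <- ch[[p]]
      if (is.null(kids) || length(kids) == 0L) next
      nc <- if (p %in% tax$coverage_off) " nc" else ""
      out <- c(out, sprintf("(%s %s%s)", p, paste(kids, collapse = " "), nc))
    }
    if (nrow(tax$edges) == 0L && length(tax$concepts) == 1L) {
      out <- c(out, sprintf("(%s)", tax$concepts))
    }
    out
  }
  lines <- c(render_tax(problem$t1), "", render_tax(problem$t2), "",
             sprintf("articulation %s", name))
  for (a in problem$articulations) {
    lines <- c(lines, sprintf("[%s %s %s]", a$left,
                              .rcc5_set_string(a$relation), a$right))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write a MIR table
#'
#' Serializes maximally-informative-relation entries as a comma-separated
#' table with one row per ordered cross-taxonomy pair: left concept (T2),
#' relation-set string, right concept (T1), provenance class, resolved
#' flag.  Rows are sorted deduced-before-inferred (with input entries
#' first within the deduced class) and lexicographically within class.
#'
#' @param entries A MIR data frame from [compute_mir()] /
#'   [classify_mir()].
#' @param file Optional path; when `NULL` the CSV text is returned.
#' @return The CSV text, invisibly when written to `file`.
#' @export
write_mir <- function(entries, file = NULL) {
  df <- data.frame(
    left = entries$left,
    relation = vapply(entries$realized, .rcc5_set_string, ""),
    right = entries$right,
    provenance = if (is.null(entries$provenance)) NA_character_ else
      entries$provenance,
    resolved = entries$resolved,
    stringsAsFactors = FALSE
  )
  rank <- match(df$provenance, c("input", "deduced", "inferred"))
  rank[is.na(rank)] <- 4L
  df <- df[order(rank, df$left, df$right), , drop = FALSE]
  txt <- c("left,relation,right,provenance,resolved",
           sprintf("%s,%s,%s,%s,%s", df$left, df$relation, df$right,
                   df$provenance, tolower(as.character(df$resolved))))
  txt <- paste0(paste(txt, collapse = "\n"), "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file, sep = "")
  invisible(txt)
}

# DOT-quote an identifier
.dot_id <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

.dot_node_attrs <- function(provenance) {
  switch(provenance,
         both = 'shape=box, style=filled, fillcolor=grey',
         T1_only = 'shape=octagon, style=filled, fillcolor=yellow',
         T2_only = 'shape=box, style=filled, fillcolor=palegreen',
         'shape=box')
}

#' Write a merge graph as DOT
#'
#' Node provenance is encoded in the conventional shapes and fills: grey
#' boxes for concepts shared by both taxonomies, yellow octagons for
#' T1-only, green rectangles for T2-only.  Inclusion edges are directed
#' parent-to-child; overlap edges are rendered undirected and dashed.
#'
#' @param graph A `merge_graph` from [containment_graph()] or
#'   [merge_concept_graph()].
#' @param style `"containment"` or `"merge"`; recorded in the graph
#'   header comment.
#' @param file Optional path; when `NULL` the DOT text is returned.
#' @return The DOT text, invisibly when written to `file`.
#' @export
write_dot <- function(graph, style = c("containment", "merge"),
                      file = NULL) {
  style <- match.arg(style)
  stopifnot(inherits(graph, "merge_graph"))
  lines <- c(sprintf("// %s graph", style), "digraph alignment {",
             "  rankdir=TB;")
  for (node in graph$nodes) {
    lab <- paste(node$labels, collapse = "\\n")
    lines <- c(lines, sprintf("  %s [label=%s, %s];", .dot_id(node$id),
                              .dot_id(lab), .dot_node_attrs(node$provenance)))
  }
  inc <- graph$inclusion
  for (k in seq_len(nrow(inc))) {
    lines <- c(lines, sprintf("  %s -> %s;", .dot_id(inc$from[k]),
                              .dot_id(inc$to[k])))
  }
  ov <- graph$overlap
  for (k in seq_len(nrow(ov))) {
    lines <- c(lines,
               sprintf("  %s -> %s [dir=none, style=dashed, constraint=false];",
                       .dot_id(ov$a[k]), .dot_id(ov$b[k])))
  }
  lines <- c(lines, "}")
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(file)) return(txt)
  writeLines(txt, file, sep = "")
  invisible(txt)
}
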