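# Ontology graph container
#
# An ontology is held in an environment so that closure caches can be
# memoised in place and invalidated when edges are mutated.  Edge semantics
# follow scoping orientation: for a "subject_narrower" relation (is_a,
# part_of) the subject is the child of the object; for a "subject_broader"
# relation (has_part) the edge is inverted — the *object* is the child —
# giving has_part its part-of-some reading while keeping traversal rootward.
# Non-scoping relations are stored inert and contribute nothing to
# parent/child sets.

SCOPE_NARROWER   <- "subject_narrower"
SCOPE_BROADER    <- "subject_broader"
SCOPE_NON_SCOPING <- "non_scoping"

default_relation_registry <- function() {
  data.frame(
    relation = c("is_a", "part_of", "has_part"),
    orientation = c(SCOPE_NARROWER, SCOPE_NARROWER, SCOPE_BROADER),
    stringsAsFactors = FALSE
  )
}

new_ontology_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- list()       # id -> list(id, name, def, namespace, obsolete, synonyms)
  g$parents <- list()     # id -> character() of parent ids (scoping edges only)
  g$children <- list()    # id -> character() of child ids
  g$edges <- data.frame(subject = character(), object = character(),
                        relation = character(), stringsAsFactors = FALSE)
  g$relations <- default_relation_registry()
  g$cache <- new.env(parent = emptyenv())
  class(g) <- "ontology_graph"
  g
}

invalidate_closures <- function(graph) {
  # whole-cache invalidation: coarse but safe, mutation is rare after parse
  graph$cache <- new.env(parent = emptyenv())
  invisible(graph)
}

relation_orientation <- function(graph, relation) {
  hit <- match(relation, graph$relations$relation)
  if (is.na(hit)) return(NA_character_)
  graph$relations$orientation[hit]
}

register_relation <- function(graph, relation, orientation = SCOPE_NON_SCOPING) {
  hit <- match(relation, graph$relations$relation)
  if (is.na(hit)) {
    graph$relations <- rbind(graph$relations, data.frame(
      relation = relation, orientation = orientation, stringsAsFactors = FALSE))
  } else if (graph$relations$orientation[hit] != orientation) {
    stop_domain(sprintf("relation '%s' already registered with orientation '%s'",
                        relation, graph$relations$orientation[hit]))
  }
  invisible(graph)
}

#' Test whether a term exists in an ontology graph
#'
#' @param graph an `ontology_graph`.
#' @param id term accession string.
#' @return `TRUE` if the (non-obsolete, namespace-passing) term is indexed.
#' @export
has_term <- function(graph, id) {
  !is.null(graph$nodes[[id]])
}

#' All term identifiers in a graph
#'
#' @param graph an `ontology_graph`.
#' @return sorted character vector of term ids.
#' @export
term_ids <- function(graph) sort_ids(names(graph$nodes))

#' Look up a parsed term record
#'
#' @param graph an `ontology_graph`.
#' @param id term accession string.
#' @return a list with fields `id`, `name`, `def`, `namespace`, `obsolete`,
#'   `synonyms`, `parents`, `children`.
#' @export
term_info <- function(graph, id) {
  node <- graph$nodes[[id]]
  if (is.null(node)) stop_domain(sprintf("unknown term id '%s'", id))
  node$parents <- sort_ids(graph$parents[[id]])
  node$children <- sort_ids(graph$children[[id]])
  node
}

add_term_node <- function(graph, node) {
  graph$nodes[[node$id]] <- node
  if (is.null(graph$parents[[node$id]])) graph$parents[[node$id]] <- character()
  if (is.null(graph$children[[node$id]])) graph$children[[node$id]] <- character()
  invisible(graph)
}

# Resolve the parent->child orientation of one edge; returns NULL for
# non-scoping relations.
edge_parent_child <- function(graph, subject, object, relation) {
  orient <- relation_orientation(graph, relation)
  if (is.na(orient) || orient == SCOPE_NON_SCOPING) return(NULL)
  if (orient == SCOPE_NARROWER) list(parent = object, child = subject)
  else list(parent = subject, child = object)  # has_part inversion
}

#' Add an edge to an ontology graph
#'
#' Both endpoints must already exist.  Scoping relations update the
#' parent/child sets (with has_part inverted); non-scoping relations are
#' stored inert.  Closure caches are invalidated.
#'
#' @param graph an `ontology_graph`.
#' @param subject,object term ids of the asserted relation
#'   (`subject relation object`).
#' @param relation relation identifier, e.g. `"is_a"`.
#' @return the graph, invisibly.
#' @export
add_edge <- function(graph, subject, object, relation) {
  if (!has_term(graph, subject) || !has_term(graph, object)) {
    stop_domain(sprintf("edge %s -[%s]-> %s references an unknown term",
                        subject, relation, object))
  }
  graph$edges <- rbind(graph$edges, data.frame(
    subject = subject, object = object, relation = relation,
    stringsAsFactors = FALSE))
  pc <- edge_parent_child(graph, subject, object, relation)
  if (!is.null(pc)) {
    graph$parents[[pc$child]] <- unique(c(graph$parents[[pc$child]], pc$parent))
    graph$children[[pc$parent]] <- unique(c(graph$children[[pc$parent]], pc$child))
  }
  invalidate_closures(graph)
}

#' Remove an edge from an ontology graph
#'
#' @inheritParams add_edge
#' @return the graph, invisibly.
#' @export
remove_edge <- function(graph, subject, object, relation) {
  hit <- which(graph$edges$subject == subject & graph$edges$object == object &
               graph$edges$relation == relation)
  if (length(hit) == 0L) {
    stop_domain(sprintf("no edge %s -[%s]-> %s in graph", subject, relation, object))
  }
  graph$edges <- graph$edges[-hit[1], , drop = FALSE]
  pc <- edge_parent_child(graph, subject, object, relation)
  if (!is.null(pc)) {
    # another stored edge may still assert the same parent/child pair
    still <- FALSE
    if (nrow(graph$edges) > 0L) {
      for (i in seq_len(nrow(graph$edges))) {
        other <- edge_parent_child(graph, graph$edges$subject[i],
                                   graph$edges$object[i], graph$edges$relation[i])
        if (!is.null(other) && other$parent == pc$parent && other$child == pc$child) {
          still <- TRUE; break
        }
      }
    }
    if (!still) {
      graph$parents[[pc$child]] <- setdiff(graph$parents[[pc$child]], pc$parent)
      graph$children[[pc$parent]] <- setdiff(graph$children[[pc$parent]], pc$child)
    }
  }
  invalidate_closures(graph)
}

# Lazily memoised transitive closure over a link map ("parents" or
# "children").  Recomputed from scratch after any edge mutation because
# mutation clears the whole cache.
closure_over <- function(graph, id, link_field) {
  if (!has_term(graph, id)) stop_domain(sprintf("unknown term id '%s'", id))
  memo_name <- paste0(link_field, ".", id)
  cached <- graph$cache[[memo_name]]
  if (!is.null(cached)) return(cached)
  links <- graph[[link_field]]
  # iterative DFS with per-node memoisation shared through graph$cache
  visit <- function(node) {
    key <- paste0(link_field, ".", node)
    got <- graph$cache[[key]]
    if (!is.null(got)) return(got)
    out <- character()
    for (nb in links[[node]]) {
      out <- c(out, nb, visit(nb))
    }
    out <- sort_ids(out)
    graph$cache[[key]] <- out
    out
  }
  visit(id)
}

#' Ancestors of a term
#'
#' All terms reachable by repeated parent hops over scoping edges (after
#' has_part inversion).  The closure is computed lazily on first access,
#' cached, and recomputed after any edge mutation.
#'
#' @param graph an `ontology_graph`.
#' @param id term accession string.
#' @return sorted character vector of ancestor ids (never contains `id`).
#' @export
ancestors <- function(graph, id) closure_over(graph, id, "parents")

#' Descendants of a term
#'
#' Mirror of [ancestors()] over child links.
#'
#' @inheritParams ancestors
#' @return sorted character vector of descendant ids.
#' @export
descendants <- function(graph, id) closure_over(graph, id, "children")

# Kahn topological check over the induced parent->child DAG; on failure,
# returns one offending cycle (as an id vector) for the error message.
find_scoping_cycle <- function(parents) {
  ids <- names(parents)
  indeg <- vapply(parents, length, integer(1))
  queue <- ids[indeg == 0L]
  seen <- 0L
  children <- list()
  for (id in ids) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }
  while (length(queue) > 0L) {
    n <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in children[[n]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(ids)) return(NULL)
  # walk parent links from any node still carrying in-degree until repeat
  start <- ids[indeg > 0L][1]
  path <- character(); node <- start
  repeat {
    if (node %in% path) {
      cyc <- path[seq(match(node, path), length(path))]
      return(c(cyc, node))
    }
    path <- c(path, node)
    nxt <- intersect(parents[[node]], ids[indeg > 0L])
    node <- nxt[[1]]
  }
}

assert_acyclic <- function(graph) {
  cyc <- find_scoping_cycle(graph$parents)
  if (!is.null(cyc)) {
    stop_domain(sprintf(
      "scoping edges form a cycle after reinterpretation: %s",
      paste(cyc, collapse = " -> ")), class = "goslicer_cycle_error")
  }
  invisible(graph)
}

#' Summarise an ontology graph
#'
#' @param graph an `ontology_graph`.
#' @return list with `term_count`, `edge_count` and a named
#'   `relation_histogram`, suitable for JSON export.
#' @export
graph_summary <- function(graph) {
  hist <- table(graph$edges$relation)
  hist <- as.list(structure(as.integer(hist), names = names(hist)))
  if (length(hist) > 0L) hist <- hist[order(names(hist))]
  list(term_count = length(graph$nodes),
       edge_count = nrow(graph$edges),
       relation_histogram = hist)
}

#' @export
print.ontology_graph <- function(x, ...) {
  s <- graph_summary(x)
  cat(sprintf("<ontology_graph> %d terms, %d edges\n", s$term_count, s$edge_count))
  if (length(s$relation_histogram)) {
    cat("  relations:",
        paste(sprintf("%s (%d)", names(s$relation_histogram),
                      unlist(s$relation_histogram)), collapse = ", "), "\n")
  }
  invisible(x)
}
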