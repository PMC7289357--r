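# Category subgraph construction
#
# Pipeline (one pass, in order): keyword seeding -> scoping-edge recreation
# -> representative election -> extension (comprehensive or conservative)
# -> constraint to the representative's descendants.  Subgraphs reference
# supergraph nodes by id and never mutate the supergraph.

#' Seed a category by keyword search
#'
#' Returns every non-obsolete term whose name OR definition contains at
#' least one keyword as a case-insensitive substring.  Synonyms are never
#' queried.
#'
#' @param graph an `ontology_graph`.
#' @param keywords non-empty character vector of keywords.
#' @return sorted character vector of seeded term ids.
#' @export
seed_by_keywords <- function(graph, keywords) {
  if (length(keywords) == 0L) stop_domain("keyword list must be non-empty")
  ids <- names(graph$nodes)
  if (length(ids) == 0L) return(character())
  names_lc <- tolower(vapply(graph$nodes, function(n) n$name, character(1)))
  defs_lc <- tolower(vapply(graph$nodes, function(n) n$def, character(1)))
  hit <- rep(FALSE, length(ids))
  for (kw in tolower(keywords)) {
    hit <- hit | grepl(kw, names_lc, fixed = TRUE) | grepl(kw, defs_lc, fixed = TRUE)
  }
  sort_ids(ids[hit])
}

# Scoping edges of the supergraph with both endpoints in `ids`, plus the
# induced parent/child maps restricted to `ids`.
local_scoping_maps <- function(graph, ids) {
  parents <- children <- stats::setNames(
    replicate(length(ids), character(), simplify = FALSE), ids)
  keep <- logical(nrow(graph$edges))
  if (nrow(graph$edges) > 0L) {
    for (i in seq_len(nrow(graph$edges))) {
      pc <- edge_parent_child(graph, graph$edges$subject[i],
                              graph$edges$object[i], graph$edges$relation[i])
      if (is.null(pc)) next
      if (pc$parent %in% ids && pc$child %in% ids) {
        keep[i] <- TRUE
        parents[[pc$child]] <- unique(c(parents[[pc$child]], pc$parent))
        children[[pc$parent]] <- unique(c(children[[pc$parent]], pc$child))
      }
    }
  }
  list(edges = graph$edges[keep, , drop = FALSE],
       parents = parents, children = children)
}

local_closure <- function(link_map, id) {
  out <- character()
  queue <- link_map[[id]]
  while (length(queue) > 0L) {
    n <- queue[[1]]; queue <- queue[-1]
    if (n %in% out) next
    out <- c(out, n)
    queue <- c(queue, link_map[[n]])
  }
  sort_ids(out)
}

#' Recreate scoping edges among a seeded term set
#'
#' Returns exactly the scoping edges of the supergraph whose two endpoints
#' (after has_part inversion) both lie in the seeded set.
#'
#' @param graph an `ontology_graph`.
#' @param seeded character vector of term ids (must exist in `graph`).
#' @return data frame with columns `subject`, `object`, `relation`.
#' @export
recreate_edges <- function(graph, seeded) {
  missing <- seeded[!vapply(seeded, has_term, logical(1), graph = graph)]
  if (length(missing) > 0L) {
    stop_domain(sprintf("seeded ids not in graph: %s",
                        paste(missing, collapse = ", ")))
  }
  local_scoping_maps(graph, seeded)$edges
}

#' Elect a category-representative term
#'
#' Candidates are seeded terms carrying at least one keyword in their
#' *name* (a keyword only in the definition does not qualify).  The
#' candidate with the most within-subgraph descendants wins, so any
#' keyword-named non-leaf outranks every leaf; a lone keyword-named leaf
#' can still represent a single-term category (an isolated concept like
#' "aggresome" forms a one-node subgraph rooted at itself).  Ties break to
#' the lexicographically smallest id so election is deterministic.
#'
#' @param graph an `ontology_graph`.
#' @param seeded seeded term ids.
#' @param keywords the category's keywords.
#' @return the representative term id.
#' @export
select_representative <- function(graph, seeded, keywords) {
  maps <- local_scoping_maps(graph, seeded)
  names_lc <- vapply(seeded, function(id) tolower(graph$nodes[[id]]$name),
                     character(1))
  has_kw <- rep(FALSE, length(seeded))
  for (kw in tolower(keywords)) has_kw <- has_kw | grepl(kw, names_lc, fixed = TRUE)
  candidates <- seeded[has_kw]
  if (length(candidates) == 0L) {
    stop_domain(paste("no representative candidate: no seeded term carries",
                      "a keyword in its name; add keywords or supply seed",
                      "terms"),
                class = "goslicer_categorization_error")
  }
  counts <- vapply(candidates, function(id) length(local_closure(maps$children, id)),
                   integer(1))
  winners <- candidates[counts == max(counts)]
  sort_ids(winners)[1]
}

new_subgraph <- function(graph, spec, seeded, representative_ids, elected) {
  maps <- local_scoping_maps(graph, seeded)
  structure(list(
    spec = spec, graph = graph,
    seeded_ids = sort_ids(seeded),
    node_ids = sort_ids(seeded),
    edges = maps$edges, parents = maps$parents, children = maps$children,
    representative_ids = sort_ids(representative_ids),
    elected = elected,
    member_ids = NULL, removed_seed_ids = NULL, members_by_rep = NULL
  ), class = "category_subgraph")
}

#' Seed a category subgraph and elect its representative
#'
#' Runs the first three pipeline stages: keyword seeding (plus any explicit
#' seed terms), scoping-edge recreation, and representative election.  When
#' the spec supplies `seed_terms`, each seed term is a representative and
#' election is skipped.
#'
#' @param graph an `ontology_graph`.
#' @param spec a [category_spec()].
#' @return an unextended `category_subgraph`.
#' @export
seed_subgraph <- function(graph, spec) {
  stopifnot(inherits(spec, "category_spec"))
  seeded <- character()
  if (length(spec$keywords) > 0L) {
    seeded <- seed_by_keywords(graph, spec$keywords)
  }
  if (length(spec$seed_terms) > 0L) {
    missing <- spec$seed_terms[!vapply(spec$seed_terms, has_term, logical(1),
                                       graph = graph)]
    if (length(missing) > 0L) {
      stop_domain(sprintf("seed terms not in graph: %s",
                          paste(missing, collapse = ", ")))
    }
    seeded <- union(seeded, spec$seed_terms)
    return(new_subgraph(graph, spec, seeded, spec$seed_terms, elected = FALSE))
  }
  rep_id <- select_representative(graph, seeded, spec$keywords)
  new_subgraph(graph, spec, seeded, rep_id, elected = TRUE)
}

refresh_subgraph_maps <- function(subgraph, node_ids) {
  maps <- local_scoping_maps(subgraph$graph, sort_ids(node_ids))
  subgraph$node_ids <- sort_ids(node_ids)
  subgraph$edges <- maps$edges
  subgraph$parents <- maps$parents
  subgraph$children <- maps$children
  subgraph
}

#' Comprehensive (greedy) subgraph extension
#'
#' Adds every supergraph descendant of the representative(s) to the
#' subgraph, then rebuilds the subgraph's scoping edges.
#'
#' @param graph an `ontology_graph` (the subgraph's supergraph).
#' @param subgraph a seeded `category_subgraph`.
#' @return the extended subgraph.
#' @export
extend_comprehensive <- function(graph, subgraph) {
  added <- unlist(lapply(subgraph$representative_ids, descendants, graph = graph))
  refresh_subgraph_maps(subgraph, union(subgraph$node_ids, added))
}

#' Conservative subgraph extension
#'
#' For each leaf of the seeded subgraph, adds only the supergraph terms
#' lying on paths between that leaf and the representative(s):
#' `intersect(ancestors(leaf), descendants(representative))`.  Descendants of
#' the representative on no leaf path are not added.
#'
#' @inheritParams extend_comprehensive
#' @return the extended subgraph.
#' @export
extend_conservative <- function(graph, subgraph) {
  leaves <- subgraph$node_ids[vapply(subgraph$node_ids,
                                     function(id) length(subgraph$children[[id]]) == 0L,
                                     logical(1))]
  added <- character()
  for (leaf in leaves) {
    anc <- ancestors(graph, leaf)
    for (rep_id in subgraph$representative_ids) {
      added <- c(added, intersect(anc, descendants(graph, rep_id)))
    }
  }
  refresh_subgraph_maps(subgraph, union(subgraph$node_ids, added))
}

#' Constrain a subgraph to its representative's descendants
#'
#' The final pipeline stage: members become the representative(s) plus
#' their within-subgraph descendants; all other seeded terms (serendipitous
#' keyword matches not rooted to the representative) move to
#' `removed_seed_ids`.
#'
#' @param subgraph an extended `category_subgraph`.
#' @return the finished subgraph, with `member_ids`, `removed_seed_ids`
#'   and per-representative member sets filled in.
#' @export
constrain_to_representative <- function(subgraph) {
  members_by_rep <- lapply(subgraph$representative_ids, function(rep_id) {
    sort_ids(c(rep_id, local_closure(subgraph$children, rep_id)))
  })
  names(members_by_rep) <- subgraph$representative_ids
  members <- sort_ids(unlist(members_by_rep))
  subgraph$members_by_rep <- members_by_rep
  subgraph$member_ids <- members
  subgraph$removed_seed_ids <- sort_ids(setdiff(subgraph$seeded_ids, members))
  subgraph <- refresh_subgraph_maps(subgraph, members)
  subgraph
}

#' Build a finished category subgraph
#'
#' Orchestrates the full pipeline: seed, recreate edges, elect (or adopt)
#' the representative, extend per the spec's mode, and constrain to the
#' representative's descendants.  Deterministic: the same graph and spec
#' always yield the same members.
#'
#' @param graph an `ontology_graph`.
#' @param spec a [category_spec()].
#' @return a finished `category_subgraph`.
#' @examples
#' obo <- c("[Term]", "id: X:1", "name: nucleus", "",
#'          "[Term]", "id: X:2", "name: nuclear membrane", "is_a: X:1")
#' g <- parse_obo(obo)
#' sg <- build_category(g, category_spec("nucleus", keywords = "nucle"))
#' sg$member_ids
#' @export
build_category <- function(graph, spec) {
  subgraph <- seed_subgraph(graph, spec)
  subgraph <- switch(spec$extension_mode,
    comprehensive = extend_comprehensive(graph, subgraph),
    conservative = extend_conservative(graph, subgraph))
  constrain_to_representative(subgraph)
}

#' Export a finished subgraph as a plain list
#'
#' Mirrors the per-category summary columns (seeded / added / removed /
#' total counts) alongside the sorted member list; suitable for JSON
#' serialization.
#'
#' @param subgraph a finished `category_subgraph`.
#' @return a named list.
#' @export
subgraph_export <- function(subgraph) {
  if (is.null(subgraph$member_ids)) {
    stop_domain("subgraph is not finished; run constrain_to_representative()")
  }
  list(
    name = subgraph$spec$name,
    representative = subgraph$representative_ids,
    members = subgraph$member_ids,
    seeded_count = length(subgraph$seeded_ids),
    added_count = length(setdiff(subgraph$member_ids, subgraph$seeded_ids)),
    removed_count = length(subgraph$removed_seed_ids),
    total_count = length(subgraph$member_ids)
  )
}

#' @export
print.category_subgraph <- function(x, ...) {
  cat(sprintf("<category_subgraph> '%s'\n", x$spec$name))
  cat(sprintf("  representative: %s%s\n",
              paste(x$representative_ids, collapse = ", "),
              if (x$elected) " (elected)" else " (user seed)"))
  cat(sprintf("  seeded: %d", length(x$seeded_ids)))
  if (!is.null(x$member_ids)) {
    cat(sprintf("  members: %d  removed seeds: %d",
                length(x$member_ids), length(x$removed_seed_ids)))
  }
  cat("\n")
  invisible(x)
}
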