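# OBO 1.2 flat-file parser
#
# Reads only the tags the categorization method needs: id, name, namespace,
# def, is_a, relationship, is_obsolete, synonym.  Everything else (xref,
# subset, alt_id, ...) is ignored silently.  Relation identifiers are
# normalised to snake_case because OBO files vary ("part of" vs "part_of").

normalize_relation <- function(rel) {
  gsub("[ -]+", "_", tolower(trimws(rel)))
}

strip_obo_comment <- function(value) {
  trimws(sub("!.*$", "", value))
}

extract_quoted <- function(value) {
  m <- regmatches(value, regexec('^"((?:[^"\\\\]|\\\\.)*)"', value))[[1]]
  if (length(m) < 2L) return(trimws(value))
  gsub('\\\\(.)', "\\1", m[2])
}

#' Parse an OBO ontology into a scoped DAG
#'
#' Builds an [ontology graph][ancestors] from OBO 1.2 text.  Scoping
#' relations get their orientation from the relation registry: `is_a` and
#' `part_of` point child-to-parent as written, while `has_part` is inverted
#' (read as "part of some") so that traversal always runs from narrower to
#' broader terms and the graph stays acyclic.  Relations outside the
#' registry are registered as non-scoping with a warning and stored inert.
#'
#' @param source path to an OBO file, a single string of OBO text, or a
#'   character vector of lines.
#' @param namespace_filter optional character vector; keep only terms in
#'   these namespaces.  Edges never join a filtered-out term.
#' @param allowed_relations optional character vector of relation
#'   identifiers; edges of any other relation are dropped.  Passing
#'   `c("is_a", "part_of")` reproduces go-basic-style scoping from a
#'   go-core file.  `NULL` (default) keeps every relation.
#' @return an `ontology_graph` containing the non-obsolete terms passing the
#'   namespace filter.
#' @examples
#' obo <- c("[Term]", "id: X:1", "name: root", "",
#'          "[Term]", "id: X:2", "name: leaf", "is_a: X:1")
#' g <- parse_obo(obo)
#' ancestors(g, "X:2")
#' @export
parse_obo <- function(source, namespace_filter = NULL, allowed_relations = NULL) {
  lines <- read_text_lines(source)
  graph <- new_ontology_graph()

  stanzas <- list()
  cur <- NULL
  cur_line <- NA_integer_
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur)) stanzas[[length(stanzas) + 1L]] <<- cur
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "") next
    if (grepl("^\\[", line)) {
      flush()
      in_term <- identical(line, "[Term]")
      if (in_term) {
        cur <- list(line = i, id = NULL, name = "", namespace = "",
                    def = "", obsolete = FALSE, synonyms = list(),
                    edges = list())
      }
      next
    }
    if (!in_term) next
    sep <- regexpr(":", line, fixed = TRUE)
    if (sep < 0L) next
    key <- substr(line, 1L, sep - 1L)
    value <- trimws(substr(line, sep + 1L, nchar(line)))
    if (key == "id") {
      cur$id <- strip_obo_comment(value)
    } else if (key == "name") {
      cur$name <- strip_obo_comment(value)
    } else if (key == "namespace") {
      cur$namespace <- strip_obo_comment(value)
    } else if (key == "def") {
      cur$def <- extract_quoted(value)
    } else if (key == "is_obsolete") {
      cur$obsolete <- identical(strip_obo_comment(value), "true")
    } else if (key == "synonym") {
      text <- extract_quoted(value)
      rest <- sub('^"(?:[^"\\\\]|\\\\.)*"\\s*', "", value)
      scope <- sub("\\s.*$", "", rest)
      cur$synonyms[[length(cur$synonyms) + 1L]] <- list(text = text, scope = scope)
    } else if (key == "is_a") {
      cur$edges[[length(cur$edges) + 1L]] <-
        list(relation = "is_a", target = strip_obo_comment(value), line = i)
    } else if (key == "relationship") {
      v <- strip_obo_comment(value)
      parts <- strsplit(v, "\\s+")[[1]]
      if (length(parts) < 2L) {
        stop_domain(sprintf("malformed relationship line %d: '%s'", i, line),
                    class = "goslicer_parse_error")
      }
      cur$edges[[length(cur$edges) + 1L]] <-
        list(relation = normalize_relation(parts[1]), target = parts[2], line = i)
    }
    # all other tags ignored
  }
  flush()

  # node pass
  for (st in stanzas) {
    if (is.null(st$id) || st$id == "") {
      stop_domain(sprintf("malformed [Term] stanza starting at line %d: missing id",
                          st$line), class = "goslicer_parse_error")
    }
    if (st$obsolete) next
    if (!is.null(namespace_filter) && !(st$namespace %in% namespace_filter)) next
    add_term_node(graph, list(id = st$id, name = st$name, def = st$def,
                              namespace = st$namespace, obsolete = FALSE,
                              synonyms = st$synonyms))
  }

  # edge pass: endpoints must both survive filtering
  warned <- character()
  for (st in stanzas) {
    if (st$obsolete || is.null(st$id) || !has_term(graph, st$id)) next
    for (e in st$edges) {
      if (!is.null(allowed_relations) && !(e$relation %in% allowed_relations)) next
      if (!has_term(graph, e$target)) next
      if (is.na(relation_orientation(graph, e$relation))) {
        if (!(e$relation %in% warned)) {
          warning(sprintf("unknown relation '%s' (line %d): treated as non-scoping",
                          e$relation, e$line), call. = FALSE)
          warned <- c(warned, e$relation)
        }
        register_relation(graph, e$relation, SCOPE_NON_SCOPING)
      }
      add_edge(graph, st$id, e$target, e$relation)
    }
  }

  assert_acyclic(graph)
  graph
}
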