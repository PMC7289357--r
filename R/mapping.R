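# Term-to-category mapping tables and GAF rewriting
#
# GAF 2.x files are plain tab-separated text with 17 columns and
# "!"-prefixed header lines.  Only five columns are read semantically:
# DB object symbol (3), GO id (5), evidence code (7), aspect (9) and
# assigned-by (15); all 17 are preserved on rewrite.

GAF_COLUMNS <- 17L
IEA_PRESET <- "IEA"

#' Build a term-to-category mapping table
#'
#' Every member of every finished subgraph maps to that subgraph's
#' representative(s).  By default, superset suppression is applied: if the
#' representative of category `c1` is itself a member of category `c2`
#' (`c1`'s subgraph nests inside `c2`'s), terms shared by both map only to
#' the nearer root `c1`, not to the enclosing `c2` — e.g. a nucleolus term
#' maps to "nucleolus", not to both "nucleolus" and "nucleus".  Pass
#' `map_supersets = TRUE` to keep both mappings.
#'
#' @param subgraphs list of finished `category_subgraph` objects built on
#'   the same supergraph.
#' @param map_supersets logical; disable superset suppression.
#' @return a `mapping_table` with `term_to_categories` (term id -> sorted
#'   representative ids) and `category_to_members` (representative id ->
#'   member id set), mutually consistent.
#' @export
build_mapping <- function(subgraphs, map_supersets = FALSE) {
  members_by_rep <- list()
  for (sg in subgraphs) {
    if (!inherits(sg, "category_subgraph") || is.null(sg$members_by_rep)) {
      stop_domain("build_mapping() needs finished category_subgraph objects")
    }
    for (rep_id in names(sg$members_by_rep)) {
      if (rep_id %in% names(members_by_rep)) {
        stop_domain(sprintf(
          "duplicate representative id '%s' across category specs", rep_id))
      }
      members_by_rep[[rep_id]] <- sg$members_by_rep[[rep_id]]
    }
  }
  reps <- names(members_by_rep)

  term_to_categories <- list()
  for (rep_id in reps) {
    for (t in members_by_rep[[rep_id]]) {
      term_to_categories[[t]] <- c(term_to_categories[[t]], rep_id)
    }
  }

  if (!map_supersets) {
    for (c2 in reps) {
      inner <- reps[reps != c2 & reps %in% members_by_rep[[c2]]]
      for (c1 in inner) {
        shared <- intersect(members_by_rep[[c1]], members_by_rep[[c2]])
        for (t in shared) {
          if (t == c2) next  # a representative always maps to its own category
          term_to_categories[[t]] <- setdiff(term_to_categories[[t]], c2)
        }
      }
    }
  }

  term_to_categories <- lapply(term_to_categories, sort_ids)
  term_to_categories <- term_to_categories[sort_ids(names(term_to_categories))]

  # rebuild the inverse so the two views stay consistent post-suppression
  category_to_members <- stats::setNames(
    replicate(length(reps), character(), simplify = FALSE), reps)
  for (t in names(term_to_categories)) {
    for (c in term_to_categories[[t]]) {
      category_to_members[[c]] <- c(category_to_members[[c]], t)
    }
  }
  category_to_members <- lapply(category_to_members, sort_ids)
  category_to_members <- category_to_members[sort_ids(names(category_to_members))]

  structure(list(term_to_categories = term_to_categories,
                 category_to_members = category_to_members),
            class = "mapping_table")
}

#' @export
print.mapping_table <- function(x, ...) {
  cat(sprintf("<mapping_table> %d terms -> %d categories\n",
              length(x$term_to_categories), length(x$category_to_members)))
  invisible(x)
}

#' Write / read a mapping table as JSON
#'
#' @param mapping a `mapping_table`.
#' @param path file path.
#' @return `path` (write) or a `mapping_table` (read), invisibly/visibly.
#' @export
write_mapping_json <- function(mapping, path) {
  jsonlite::write_json(unclass(mapping), path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_mapping_json
#' @export
read_mapping_json <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("mapping file not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  structure(list(
    term_to_categories = lapply(raw$term_to_categories, unlist),
    category_to_members = lapply(raw$category_to_members, unlist)
  ), class = "mapping_table")
}

split_gaf_line <- function(line, lineno) {
  # column count from tab count: strsplit drops trailing empty fields
  ncols <- lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE))) + 1L
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(fields) < ncols) {
    fields <- c(fields, rep("", ncols - length(fields)))
  }
  if (length(fields) != GAF_COLUMNS) {
    stop_domain(sprintf("GAF line %d: expected %d tab-separated columns, found %d",
                        lineno, GAF_COLUMNS, length(fields)),
                class = "goslicer_gaf_error")
  }
  fields
}

#' Map a GAF onto category-defining terms
#'
#' Rewrites each annotation record whose GO id is in the mapping table,
#' replacing the fine-grained term with the category-defining term (one
#' output record per category, in sorted category order).  Records whose
#' evidence code is in `evidence_exclude` are dropped before mapping.
#' Records whose GO id is not in the table are returned verbatim as the
#' unmapped audit list.  Header lines beginning `!` pass through unchanged.
#'
#' @param gaf_source GAF 2.x text (path, string, or lines).
#' @param mapping a `mapping_table` from [build_mapping()].
#' @param evidence_exclude optional character vector of evidence codes to
#'   drop (e.g. `"IEA"`); default none.
#' @return list with `mapped` (output GAF lines, headers included),
#'   `unmapped` (original unmapped record lines) and `counts`
#'   (input_records, mapped_records, unmapped_records, evidence_dropped).
#' @export
map_gaf <- function(gaf_source, mapping, evidence_exclude = NULL) {
  if (!inherits(mapping, "mapping_table")) stop_domain("mapping must be a mapping_table")
  if (length(mapping$term_to_categories) == 0L) {
    stop_domain("mapping table is empty")
  }
  lines <- read_text_lines(gaf_source)
  mapped <- character()
  unmapped <- character()
  n_input <- 0L; n_mapped <- 0L; n_dropped <- 0L
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (startsWith(line, "!")) {
      mapped <- c(mapped, line)
      next
    }
    if (line == "") next
    fields <- split_gaf_line(line, i)
    n_input <- n_input + 1L
    if (!is.null(evidence_exclude) && fields[7] %in% evidence_exclude) {
      n_dropped <- n_dropped + 1L
      next
    }
    cats <- mapping$term_to_categories[[fields[5]]]
    if (is.null(cats)) {
      unmapped <- c(unmapped, line)
      next
    }
    n_mapped <- n_mapped + 1L
    for (c in cats) {
      out <- fields
      out[5] <- c
      mapped <- c(mapped, paste(out, collapse = "\t"))
    }
  }
  list(mapped = mapped, unmapped = unmapped,
       counts = list(input_records = n_input, mapped_records = n_mapped,
                     unmapped_records = length(unmapped),
                     evidence_dropped = n_dropped))
}

#' Aggregate mapped categories per gene symbol
#'
#' Collects, for each DB object symbol (GAF column 3, matched
#' case-sensitively), the set of category ids its annotations map to.
#' Genes whose annotations are all unmapped get the empty set.
#'
#' @inheritParams map_gaf
#' @return named list: gene symbol -> sorted character vector of category
#'   ids (possibly empty).
#' @export
gene_category_sets <- function(gaf_source, mapping, evidence_exclude = NULL) {
  if (!inherits(mapping, "mapping_table")) stop_domain("mapping must be a mapping_table")
  if (length(mapping$term_to_categories) == 0L) {
    stop_domain("mapping table is empty")
  }
  lines <- read_text_lines(gaf_source)
  sets <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (line == "" || startsWith(line, "!")) next
    fields <- split_gaf_line(line, i)
    if (!is.null(evidence_exclude) && fields[7] %in% evidence_exclude) next
    gene <- fields[3]
    if (is.null(sets[[gene]])) sets[[gene]] <- character()
    cats <- mapping$term_to_categories[[fields[5]]]
    if (!is.null(cats)) sets[[gene]] <- union(sets[[gene]], cats)
  }
  sets <- lapply(sets, sort_ids)
  sets[sort_ids(names(sets))]
}
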