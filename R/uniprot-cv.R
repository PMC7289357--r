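# UniProt subcellular-location controlled-vocabulary parser
#
# The CV is a line-prefixed flat file with records terminated by "//":
# an identifier line, an accession line, hierarchy lines (is-a and
# part-of, referencing parent identifiers), and GO cross-reference lines.
# Terms without parents are category-defining roots; each root maps to
# the GO cross-references of all its recursive children.  Terms lacking a
# GO cross-reference are traversed for connectivity but excluded from the
# final mapping.

#' Parse the UniProt subcellular-location controlled vocabulary
#'
#' @param source CV flat-file text (path, string, or lines).
#' @param prefixes line-prefix codes for the dialect; defaults target the
#'   UniProt subcellular-location vocabulary (`ID` identifier, `AC`
#'   accession, `HI` is-a parents, `HP` part-of parents, `GO`
#'   cross-reference, `//` record terminator).
#' @return a `mapping_table`: each root term's GO cross-reference maps to
#'   the cross-references of the root and all recursive children.
#' @examples
#' cv <- c("ID   Nucleus.", "AC   SL-0191", "GO   GO:0005634", "//")
#' parse_uniprot_cv(cv)$category_to_members
#' @export
parse_uniprot_cv <- function(source,
                             prefixes = list(identifier = "ID", accession = "AC",
                                             is_a = "HI", part_of = "HP",
                                             go = "GO", end = "//")) {
  lines <- read_text_lines(source)
  terms <- list()
  cur <- NULL
  cur_start <- NA_integer_
  flush <- function(lineno) {
    if (is.null(cur)) return(invisible())
    if (is.null(cur$identifier)) {
      stop_domain(sprintf(
        "CV record ending at line %d is missing its identifier line", lineno),
        class = "goslicer_parse_error")
    }
    terms[[cur$identifier]] <<- cur
    cur <<- NULL
  }
  strip_dot <- function(x) sub("\\.\\s*$", "", trimws(x))
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (trimws(line) == "") next
    if (startsWith(line, prefixes$end)) { flush(i); next }
    code <- sub("\\s.*$", "", line)
    value <- trimws(sub("^\\S+\\s*", "", line))
    if (is.null(cur)) { cur <- list(parents = character(), go_xref = NA_character_)
                        cur_start <- i }
    if (code == prefixes$identifier) {
      cur$identifier <- strip_dot(value)
    } else if (code == prefixes$accession) {
      cur$accession <- strip_dot(value)
    } else if (code == prefixes$is_a || code == prefixes$part_of) {
      parents <- strsplit(strip_dot(value), ";", fixed = TRUE)[[1]]
      cur$parents <- c(cur$parents, trimws(parents))
    } else if (code == prefixes$go) {
      m <- regmatches(value, regexpr("GO:[0-9]+", value))
      if (length(m) == 1L) cur$go_xref <- m
    }
  }
  flush(length(lines))

  # child links from parent references; unknown parents are tolerated
  children <- stats::setNames(
    replicate(length(terms), character(), simplify = FALSE), names(terms))
  has_parent <- stats::setNames(logical(length(terms)), names(terms))
  for (nm in names(terms)) {
    for (p in terms[[nm]]$parents) {
      if (!is.null(terms[[p]])) {
        children[[p]] <- unique(c(children[[p]], nm))
        has_parent[[nm]] <- TRUE
      }
    }
  }

  parent_map <- lapply(terms, function(t) intersect(t$parents, names(terms)))
  cyc <- find_scoping_cycle(parent_map)
  if (!is.null(cyc)) {
    stop_domain(sprintf("controlled vocabulary hierarchy contains a cycle: %s",
                        paste(cyc, collapse = " -> ")),
                class = "goslicer_cycle_error")
  }

  roots <- names(terms)[!has_parent]
  category_to_members <- list()
  for (root in roots) {
    root_go <- terms[[root]]$go_xref
    if (is.na(root_go)) next
    members <- c(root, local_closure(children, root))
    gos <- vapply(members, function(nm) terms[[nm]]$go_xref, character(1))
    category_to_members[[root_go]] <- sort_ids(gos[!is.na(gos)])
  }
  category_to_members <- category_to_members[sort_ids(names(category_to_members))]

  term_to_categories <- list()
  for (c in names(category_to_members)) {
    for (t in category_to_members[[c]]) {
      term_to_categories[[t]] <- sort_ids(c(term_to_categories[[t]], c))
    }
  }
  term_to_categories <- term_to_categories[sort_ids(names(term_to_categories))]

  structure(list(term_to_categories = term_to_categories,
                 category_to_members = category_to_members),
            class = "mapping_table")
}
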