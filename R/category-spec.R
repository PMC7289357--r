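# Category specifications

#' Define a category
#'
#' A category is defined by keywords (matched case-insensitively as plain
#' substrings against term names and definitions) and/or explicit seed
#' terms.  When seed terms are given they become the category
#' representative(s) directly and representative election is skipped.
#'
#' @param name category label.
#' @param keywords character vector of keywords (lower-cased on storage).
#' @param seed_terms optional character vector of term ids.
#' @param extension_mode `"comprehensive"` (all supergraph descendants of
#'   the representative join the subgraph) or `"conservative"` (only
#'   intermediate terms on paths from subgraph leaves to the
#'   representative).
#' @return a `category_spec` object.
#' @export
category_spec <- function(name, keywords = character(), seed_terms = character(),
                          extension_mode = c("comprehensive", "conservative")) {
  extension_mode <- match.arg(extension_mode)
  keywords <- tolower(as.character(keywords))
  seed_terms <- as.character(seed_terms)
  if (length(keywords) == 0L && length(seed_terms) == 0L) {
    stop_domain("a category needs at least one keyword or one seed term")
  }
  structure(list(name = name, keywords = keywords, seed_terms = seed_terms,
                 extension_mode = extension_mode),
            class = "category_spec")
}

#' Read category specifications from a config file
#'
#' The file is a JSON array; each entry has `name`, optional `keywords`,
#' optional `seed_terms`, and optional `extension_mode` (default
#' comprehensive).
#'
#' @param path path to the JSON spec file.
#' @return list of [category_spec()] objects.
#' @export
read_category_specs <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("category spec file not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (length(raw) == 0L) stop_io(sprintf("category spec file is empty: %s", path))
  lapply(raw, function(entry) {
    if (is.null(entry$name)) stop_io("category spec entry without a name")
    category_spec(
      name = entry$name,
      keywords = if (is.null(entry$keywords)) character() else unlist(entry$keywords),
      seed_terms = if (is.null(entry$seed_terms)) character() else unlist(entry$seed_terms),
      extension_mode = if (is.null(entry$extension_mode)) "comprehensive"
                       else entry$extension_mode
    )
  })
}
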