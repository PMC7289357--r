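#' @keywords internal
"_PACKAGE"

# Classed conditions: domain errors exit 1 from the CLI, I/O and usage
# errors exit 2.
stop_domain <- function(msg, class = character()) {
  stop(structure(
    class = c(class, "goslicer_domain_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_io <- function(msg, class = character()) {
  stop(structure(
    class = c(class, "goslicer_io_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# All serialized id sets are sorted lexicographically (byte order, stable
# across locales) so repeated runs are byte-identical.
sort_ids <- function(x) {
  if (length(x) == 0L) return(character())
  sort(unique(as.character(x)), method = "radix")
}

# Accept a file path, a single string with embedded newlines, or a
# character vector of lines.
read_text_lines <- function(source) {
  if (is.character(source) && length(source) == 1L && !grepl("\n", source, fixed = TRUE) &&
      file.exists(source)) {
    return(readLines(source, warn = FALSE))
  }
  if (is.character(source)) {
    if (length(source) == 1L) return(strsplit(source, "\n", fixed = TRUE)[[1]])
    return(source)
  }
  if (inherits(source, "connection")) return(readLines(source, warn = FALSE))
  stop_io("cannot read source: expected a file path, text, or connection")
}

write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
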