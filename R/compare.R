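# Subgraph and annotation-source comparison
#
# Two set metrics compare category subgraphs built by different methods:
# the inclusion index I = |S_n intersect S_g| / |S_n|, where S_n is the
# non-reference (other-method) set and S_g the reference set, and the
# Jaccard index |intersect| / |union|.  When S_n is fully contained in S_g,
# I = 1 and Jaccard = |S_n| / |S_g|.

#' Inclusion index between two term sets
#'
#' `I = |intersect(set_n, set_g)| / |set_n|`: the fraction of the
#' non-reference set contained in the reference set.  The asymmetry
#' matters — callers must pass the non-reference (other-method) set as
#' `set_n`.
#'
#' @param set_n non-reference member set (non-empty character vector).
#' @param set_g reference member set.
#' @return a number in \[0, 1\].
#' @export
inclusion_index <- function(set_n, set_g) {
  set_n <- unique(as.character(set_n))
  set_g <- unique(as.character(set_g))
  if (length(set_n) == 0L) {
    stop_domain("inclusion index undefined for an empty non-reference set")
  }
  length(intersect(set_n, set_g)) / length(set_n)
}

#' Jaccard index between two term sets
#'
#' @param set_a,set_b member sets; at least one must be non-empty.
#' @return `|intersect| / |union|`, a number in \[0, 1\].
#' @export
jaccard_index <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  u <- union(set_a, set_b)
  if (length(u) == 0L) stop_domain("Jaccard index undefined for two empty sets")
  length(intersect(set_a, set_b)) / length(u)
}

#' Compare two category member sets
#'
#' @param set_n non-reference member set.
#' @param set_g reference member set.
#' @return a `set_comparison` list: `inclusion_index`, `jaccard_index`,
#'   `size_n`, `size_g`, `intersection_size`.
#' @export
compare_sets <- function(set_n, set_g) {
  set_n <- unique(as.character(set_n))
  set_g <- unique(as.character(set_g))
  structure(list(
    inclusion_index = inclusion_index(set_n, set_g),
    jaccard_index = jaccard_index(set_n, set_g),
    size_n = length(set_n),
    size_g = length(set_g),
    intersection_size = length(intersect(set_n, set_g))
  ), class = "set_comparison")
}

#' @export
print.set_comparison <- function(x, ...) {
  cat(sprintf("<set_comparison> I = %.6g, Jaccard = %.6g (|n| = %d, |g| = %d, |intersect| = %d)\n",
              x$inclusion_index, x$jaccard_index, x$size_n, x$size_g,
              x$intersection_size))
  invisible(x)
}

AGREEMENT_CLASSES <- c("complete", "partial", "partial_superset", "none",
                       "no_annotation")

#' Classify per-gene agreement between two annotation sources
#'
#' Each gene of the experimental source is assigned exactly one of five
#' mutually exclusive classes against the knowledgebase source:
#' `no_annotation` (gene absent from the knowledgebase), `complete` (the
#' two category sets are equal), `partial_superset` (the knowledgebase set
#' strictly contains the experimental set), `partial` (some but not the
#' above overlap), `none` (disjoint sets).  Per-category involvement
#' counts tally, within each class, every experimental category of every
#' gene in that class — so category sums exceed gene counts.
#'
#' @param experimental named list: gene -> non-empty category id set.
#' @param knowledgebase named list: gene -> category id set.
#' @return an `agreement_report`: `classes` (named character per gene),
#'   `class_counts`, and `involvement` (category x class count matrix).
#' @export
classify_agreement <- function(experimental, knowledgebase) {
  if (length(experimental) == 0L) stop_domain("experimental gene list is empty")
  genes <- names(experimental)
  classes <- character(length(genes)); names(classes) <- genes
  for (g in genes) {
    exp_set <- unique(as.character(experimental[[g]]))
    if (length(exp_set) == 0L) {
      stop_domain(sprintf("gene '%s' has an empty experimental category set", g))
    }
    kb_set <- unique(as.character(knowledgebase[[g]]))
    if (is.null(knowledgebase[[g]]) || length(kb_set) == 0L) {
      classes[[g]] <- "no_annotation"
    } else if (setequal(kb_set, exp_set)) {
      classes[[g]] <- "complete"
    } else if (all(exp_set %in% kb_set)) {
      classes[[g]] <- "partial_superset"
    } else if (length(intersect(kb_set, exp_set)) > 0L) {
      classes[[g]] <- "partial"
    } else {
      classes[[g]] <- "none"
    }
  }
  class_counts <- vapply(AGREEMENT_CLASSES,
                         function(cl) sum(classes == cl), integer(1))
  all_cats <- sort_ids(unlist(experimental))
  involvement <- matrix(0L, nrow = length(all_cats), ncol = length(AGREEMENT_CLASSES),
                        dimnames = list(all_cats, AGREEMENT_CLASSES))
  for (g in genes) {
    for (cat in unique(as.character(experimental[[g]]))) {
      involvement[cat, classes[[g]]] <- involvement[cat, classes[[g]]] + 1L
    }
  }
  structure(list(classes = classes, class_counts = class_counts,
                 involvement = involvement),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  for (cl in names(x$class_counts)) {
    cat(sprintf("  %-16s %d\n", cl, x$class_counts[[cl]]))
  }
  invisible(x)
}

#' Remap gene category sets onto more generic categories
#'
#' Applies a category -> generic-category map to every gene's set
#' (deduplicating), e.g. folding "actin cytoskeleton" and "centrosome"
#' into "cytoskeleton" to rectify granularity differences between sources.
#'
#' @param category_sets named list: gene -> category id set.
#' @param generic_map named character vector: category id -> generic id;
#'   must cover every observed category.
#' @return named list: gene -> sorted generic category set.
#' @export
remap_generic <- function(category_sets, generic_map) {
  observed <- unique(unlist(category_sets, use.names = FALSE))
  missing <- setdiff(observed, names(generic_map))
  if (length(missing) > 0L) {
    stop_domain(sprintf("generic map does not cover: %s",
                        paste(sort_ids(missing), collapse = ", ")))
  }
  lapply(category_sets, function(s) sort_ids(unname(generic_map[as.character(s)])))
}

#' Write a subgraph comparison report as TSV
#'
#' One row per category: name, representative id, inclusion index, Jaccard
#' index, reference size, non-reference size.  Indices are printed to six
#' significant figures.
#'
#' @param comparisons named list of `set_comparison` objects (names are
#'   category labels).
#' @param representatives optional named character vector of representative
#'   ids, keyed like `comparisons`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(comparisons, path, representatives = NULL) {
  header <- paste("category", "representative", "inclusion_index",
                  "jaccard_index", "size_g", "size_n", sep = "\t")
  rows <- vapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    rep_id <- if (!is.null(representatives) && nm %in% names(representatives))
      representatives[[nm]] else ""
    paste(nm, rep_id, signif(cmp$inclusion_index, 6), signif(cmp$jaccard_index, 6),
          cmp$size_g, cmp$size_n, sep = "\t")
  }, character(1))
  write_lines_lf(c(header, rows), path)
}

#' Write an agreement report as TSV
#'
#' Per-category involvement counts by agreement class, with a final totals
#' row of per-class gene counts.
#'
#' @param report an `agreement_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_agreement_tsv <- function(report, path) {
  header <- paste(c("category", AGREEMENT_CLASSES), collapse = "\t")
  rows <- vapply(rownames(report$involvement), function(cat) {
    paste(c(cat, report$involvement[cat, AGREEMENT_CLASSES]), collapse = "\t")
  }, character(1))
  totals <- paste(c("total_genes", report$class_counts[AGREEMENT_CLASSES]),
                  collapse = "\t")
  write_lines_lf(c(header, rows, totals), path)
}

#' Write set memberships as an UpSet-style TSV matrix
#'
#' Terms in rows, sets in columns, cells 0/1; for external intersection
#' plotting.
#'
#' @param sets named list of member id vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_membership_matrix <- function(sets, path) {
  all_ids <- sort_ids(unlist(sets, use.names = FALSE))
  header <- paste(c("term", names(sets)), collapse = "\t")
  rows <- vapply(all_ids, function(id) {
    paste(c(id, vapply(sets, function(s) as.integer(id %in% s), integer(1))),
          collapse = "\t")
  }, character(1))
  write_lines_lf(c(header, rows), path)
}
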