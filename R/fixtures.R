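# Synthetic ontology and GAF generators
#
# Fixtures emulate the structural features the categorizer must handle: a
# multi-relation DAG (is_a / part_of / has_part mix), keyword-bearing names
# and definitions, cross-category part_of links, and decoy terms that match
# keywords only in their definitions and therefore get seeded but removed
# at the constraint stage.  Ground truth is computed by construction,
# independent of the categorizer.

FIXTURE_KEYWORD_POOL <- c("nucleus", "mitochond", "vesicle", "ribosome",
                          "golgi", "lysosome", "chromosome", "endosome",
                          "cytoskel", "membrane")

with_fixture_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic ontology fixture
#'
#' @param n_categories number of keyword-named category branches.
#' @param depth levels below each category root (0 = root-only category).
#' @param branching children per internal node.
#' @param has_part_fraction fraction of branch edges emitted as
#'   `parent has_part child` (inverted scoping) instead of
#'   `child is_a/part_of parent`.
#' @param cross_links count of inter-category part_of edges (always from a
#'   higher-index category into a lower-index one, so the graph stays
#'   acyclic).
#' @param decoy_terms count of terms outside any category branch whose
#'   *definitions* mention keywords — seeded by keyword search but never
#'   rooted to a representative.
#' @param rng_seed integer seed; same seed, same bytes.
#' @return a `fixture_spec` object.
#' @export
fixture_spec <- function(n_categories = 3, depth = 3, branching = 2,
                         has_part_fraction = 0.15, cross_links = 0,
                         decoy_terms = 4, rng_seed = 1) {
  stopifnot(n_categories >= 1, n_categories <= length(FIXTURE_KEYWORD_POOL),
            depth >= 0, branching >= 1,
            has_part_fraction >= 0, has_part_fraction <= 1,
            cross_links >= 0, decoy_terms >= 0)
  if (cross_links > 0 && n_categories < 2) {
    stop_domain("cross links need at least two categories")
  }
  structure(list(n_categories = n_categories, depth = depth,
                 branching = branching, has_part_fraction = has_part_fraction,
                 cross_links = cross_links, decoy_terms = decoy_terms,
                 rng_seed = rng_seed),
            class = "fixture_spec")
}

fixture_id <- function(i) sprintf("GO:%07d", i)

#' Generate a synthetic ontology with known category ground truth
#'
#' Emits OBO 1.2 text plus per-category ground truth: the expected member
#' set under full scoping, the member set when has_part edges are excluded
#' (go-basic-style scoping), the keyword-seeded set, and the expected
#' removed-seed set.  All of it is derived from the generated edge list by
#' direct reachability, never from the categorizer.
#'
#' @param spec a [fixture_spec()].
#' @return list with `obo` (character lines), `ground_truth` (per-category
#'   list with `keyword`, `root`, `members`, `members_basic`, `seeded`,
#'   `removed`), and `spec`.
#' @export
generate_ontology <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_fixture_seed(spec$rng_seed, {
    keywords <- FIXTURE_KEYWORD_POOL[seq_len(spec$n_categories)]
    nodes <- list()   # id -> list(name, def)
    next_id <- 0L
    new_node <- function(name, def) {
      next_id <<- next_id + 1L
      id <- fixture_id(next_id)
      nodes[[id]] <<- list(name = name, def = def)
      id
    }
    # parent/child orientation recorded at creation; `stanza_rel` says how
    # the edge is serialized in OBO text
    edge_parent <- character(); edge_child <- character()
    edge_rel <- character()
    add_fixture_edge <- function(parent, child, relation) {
      edge_parent <<- c(edge_parent, parent)
      edge_child <<- c(edge_child, child)
      edge_rel <<- c(edge_rel, relation)
    }

    root <- new_node("fixture root entity", "The top-level fixture term.")
    cat_nodes <- list()
    cat_root <- character(spec$n_categories)
    for (k in seq_len(spec$n_categories)) {
      kw <- keywords[k]
      r <- new_node(sprintf("fixture %s assembly", kw),
                    sprintf("Root of the %s branch.", kw))
      add_fixture_edge(root, r, "is_a")
      cat_root[k] <- r
      level_nodes <- r
      all_nodes <- r
      if (spec$depth > 0) {
        for (lvl in seq_len(spec$depth)) {
          next_level <- character()
          for (parent in level_nodes) {
            for (j in seq_len(spec$branching)) {
              nd <- new_node(
                sprintf("fixture %s level%d unit%d", kw, lvl, length(next_level) + 1L),
                sprintf("A %s-related fixture term at level %d.", kw, lvl))
              rel <- if (stats::runif(1) < spec$has_part_fraction) "has_part"
                     else sample(c("is_a", "part_of"), 1)
              add_fixture_edge(parent, nd, rel)
              next_level <- c(next_level, nd)
            }
          }
          all_nodes <- c(all_nodes, next_level)
          level_nodes <- next_level
        }
      }
      cat_nodes[[k]] <- all_nodes
    }

    # inter-category links: node from category i becomes part_of a node in
    # category j < i, layering the trees so no cycle can form
    if (spec$cross_links > 0) {
      for (l in seq_len(spec$cross_links)) {
        i <- sample(2:spec$n_categories, 1)
        j <- sample(seq_len(i - 1L), 1)
        src <- sample(setdiff(cat_nodes[[i]], cat_root[i]), 1)
        dst <- sample(cat_nodes[[j]], 1)
        add_fixture_edge(dst, src, "part_of")
      }
    }

    decoys <- character()
    if (spec$decoy_terms > 0) {
      shelf <- new_node("fixture decoy shelf", "Holds decoy fixture terms.")
      add_fixture_edge(root, shelf, "is_a")
      for (d in seq_len(spec$decoy_terms)) {
        kw <- keywords[((d - 1L) %% spec$n_categories) + 1L]
        decoys <- c(decoys, new_node(
          sprintf("fixture decoy item %d", d),
          sprintf("Spurious mention of %s in a definition.", kw)))
        add_fixture_edge(shelf, decoys[d], "is_a")
      }
    }

    # --- ground truth by direct reachability over the generated edges ---
    reach <- function(start, use_has_part) {
      keep <- if (use_has_part) rep(TRUE, length(edge_rel)) else edge_rel != "has_part"
      out <- character(); queue <- start
      while (length(queue) > 0L) {
        n <- queue[[1]]; queue <- queue[-1]
        kids <- edge_child[keep & edge_parent == n]
        kids <- setdiff(kids, out)
        out <- c(out, kids)
        queue <- c(queue, kids)
      }
      sort_ids(out)
    }
    all_ids <- names(nodes)
    names_lc <- tolower(vapply(nodes, `[[`, character(1), "name"))
    defs_lc <- tolower(vapply(nodes, `[[`, character(1), "def"))
    ground_truth <- list()
    for (k in seq_len(spec$n_categories)) {
      kw <- keywords[k]
      members <- sort_ids(c(cat_root[k], reach(cat_root[k], TRUE)))
      members_basic <- sort_ids(c(cat_root[k], reach(cat_root[k], FALSE)))
      seeded <- sort_ids(all_ids[grepl(kw, names_lc, fixed = TRUE) |
                                 grepl(kw, defs_lc, fixed = TRUE)])
      ground_truth[[kw]] <- list(
        keyword = kw, root = cat_root[k],
        members = members, members_basic = members_basic,
        seeded = seeded, removed = sort_ids(setdiff(seeded, members)))
    }

    # --- serialize as OBO 1.2 ---
    obo <- c("format-version: 1.2",
             sprintf("data-version: fixture/seed-%d", spec$rng_seed), "")
    for (id in all_ids) {
      stanza <- c("[Term]",
                  paste0("id: ", id),
                  paste0("name: ", nodes[[id]]$name),
                  "namespace: cellular_component",
                  sprintf("def: \"%s\" []", nodes[[id]]$def))
      up <- which(edge_child == id & edge_rel != "has_part")
      for (e in up) {
        if (edge_rel[e] == "is_a") {
          stanza <- c(stanza, paste0("is_a: ", edge_parent[e]))
        } else {
          stanza <- c(stanza, sprintf("relationship: %s %s", edge_rel[e],
                                      edge_parent[e]))
        }
      }
      down <- which(edge_parent == id & edge_rel == "has_part")
      for (e in down) {
        stanza <- c(stanza, sprintf("relationship: has_part %s", edge_child[e]))
      }
      obo <- c(obo, stanza, "")
    }

    list(obo = obo, ground_truth = ground_truth, spec = spec,
         decoys = sort_ids(decoys))
  })
}

#' Write a fixture manifest (spec + ground truth) as JSON
#'
#' @param fixture result of [generate_ontology()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fixture_manifest <- function(fixture, path) {
  jsonlite::write_json(
    list(spec = unclass(fixture$spec), ground_truth = fixture$ground_truth,
         decoys = fixture$decoys),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Generate a toy GAF with known gene-to-category ground truth
#'
#' Each gene is annotated to terms drawn from the fixture's category member
#' sets, so the expected output of [gene_category_sets()] is known by
#' construction.  A `noise` fraction of records (exactly
#' `floor(noise * n_records)`) get GO ids absent from the ontology and are
#' therefore unmappable.
#'
#' @param gene_count number of genes.
#' @param ground_truth the `ground_truth` element of [generate_ontology()].
#' @param noise fraction of records made unmappable.
#' @param rng_seed integer seed.
#' @param annotations_per_gene records per gene.
#' @param evidence evidence code written in column 7 (recycled over genes).
#' @return list with `gaf` (lines, header included), `truth` (gene ->
#'   annotated term ids), `expected_categories` (gene -> category root ids,
#'   noise excluded), and `noise_lines` (indices into the record sequence).
#' @export
generate_gaf <- function(gene_count, ground_truth, noise = 0, rng_seed = 1,
                         annotations_per_gene = 2, evidence = "EXP") {
  stopifnot(gene_count >= 1, noise >= 0, noise < 1)
  with_fixture_seed(rng_seed, {
    cats <- names(ground_truth)
    genes <- sprintf("GENE%03d", seq_len(gene_count))
    records <- list()
    truth <- stats::setNames(replicate(gene_count, character(), simplify = FALSE),
                             genes)
    rec_gene <- character()
    for (g in seq_len(gene_count)) {
      for (a in seq_len(annotations_per_gene)) {
        kw <- sample(cats, 1)
        term <- sample(ground_truth[[kw]]$members, 1)
        truth[[genes[g]]] <- union(truth[[genes[g]]], term)
        ev <- evidence[((g - 1L) %% length(evidence)) + 1L]
        records[[length(records) + 1L]] <- c(
          "FIX", sprintf("FIX:%s", genes[g]), genes[g], "", term,
          "FIX:0000001", ev, "", "C", "fixture gene product", "",
          "protein", "taxon:9606", "20160112", "FIX", "", "")
        rec_gene <- c(rec_gene, genes[g])
      }
    }
    n_rec <- length(records)
    n_noise <- floor(noise * n_rec)
    noise_idx <- if (n_noise > 0) sort(sample.int(n_rec, n_noise)) else integer()
    for (i in noise_idx) {
      bogus <- sprintf("GO:9%06d", i)
      records[[i]][5] <- bogus
    }
    # expected category sets exclude the noisy records
    expected <- stats::setNames(replicate(gene_count, character(), simplify = FALSE),
                                genes)
    for (i in seq_len(n_rec)) {
      if (i %in% noise_idx) next
      term <- records[[i]][5]
      for (kw in cats) {
        if (term %in% ground_truth[[kw]]$members) {
          expected[[rec_gene[i]]] <- union(expected[[rec_gene[i]]],
                                           ground_truth[[kw]]$root)
        }
      }
    }
    gaf <- c("!gaf-version: 2.1",
             sprintf("!generated-by: goslicer fixture (seed %d)", rng_seed),
             vapply(records, paste, character(1), collapse = "\t"))
    list(gaf = gaf, truth = lapply(truth, sort_ids),
         expected_categories = lapply(expected, sort_ids),
         noise_lines = noise_idx)
  })
}
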