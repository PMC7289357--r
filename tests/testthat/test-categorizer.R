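# Category subgraph construction

# small nucleus-flavoured ontology used across several tests:
#   N:1 "cell nucleus" with a 4-deep chain of nucle* descendants,
#   N:6 "nuclear membrane" branch of its own, plus unrelated terms and a
#   decoy mentioning the keyword only in its definition
nucleus_obo <- function() {
  c("[Term]", "id: N:0", "name: cell", "",
    "[Term]", "id: N:1", "name: cell nucleus", "is_a: N:0", "",
    "[Term]", "id: N:2", "name: nucleolus", "relationship: part_of N:1", "",
    "[Term]", "id: N:3", "name: nucleoplasm", "relationship: part_of N:1", "",
    "[Term]", "id: N:4", "name: nucleolar rim", "is_a: N:2", "",
    "[Term]", "id: N:6", "name: nuclear membrane", "is_a: N:1", "",
    "[Term]", "id: N:7", "name: nuclear membrane leaflet", "is_a: N:6", "",
    "[Term]", "id: X:1", "name: cytoplasm", "is_a: N:0", "",
    "[Term]", "id: X:2", "name: decoy widget",
    "def: \"unrelated but mentions nucleus here\" []", "is_a: X:1", "")
}

test_that("keyword seeding scans names and definitions, case-insensitively", {
  g <- parse_obo(nucleus_obo())
  expect_length(seed_by_keywords(g, "zzzz"), 0)
  hits <- seed_by_keywords(g, "nucle")
  expect_setequal(hits, c("N:1", "N:2", "N:3", "N:4", "N:6", "N:7", "X:2"))
  expect_true("X:2" %in% seed_by_keywords(g, "NUCLEUS"))  # definition match
  expect_error(seed_by_keywords(g, character()), "non-empty",
               class = "goslicer_domain_error")
})

test_that("recreate_edges keeps only scoping edges with both endpoints seeded", {
  g <- parse_obo(seven_term_obo())
  expect_equal(nrow(recreate_edges(g, "A")), 0)
  e <- recreate_edges(g, c("A", "B", "D"))
  expect_setequal(paste(e$subject, e$relation, e$object),
                  c("B is_a A", "A has_part D"))
  # C part_of A absent when C is not seeded
  e2 <- recreate_edges(g, c("A", "B"))
  expect_equal(paste(e2$subject, e2$relation, e2$object), "B is_a A")
})

test_that("representative election maximises within-subgraph descendants", {
  g <- parse_obo(nucleus_obo())
  seeded <- seed_by_keywords(g, "nucle")
  # "cell nucleus" has 5 within-subgraph descendants, "nuclear membrane" 1
  expect_equal(select_representative(g, seeded, "nucle"), "N:1")
  # keyword only in definitions -> no candidate
  expect_error(select_representative(g, "X:2", "nucle"),
               class = "goslicer_categorization_error")
})

test_that("election ties break to the lexicographically smallest id", {
  obo <- c("[Term]", "id: T:2", "name: twin alpha", "",
           "[Term]", "id: T:1", "name: twin beta", "",
           "[Term]", "id: T:3", "name: twin leaf a", "is_a: T:2", "",
           "[Term]", "id: T:4", "name: twin leaf b", "is_a: T:1", "")
  g <- parse_obo(obo)
  seeded <- seed_by_keywords(g, "twin")
  expect_equal(select_representative(g, seeded, "twin"), "T:1")
})

test_that("comprehensive extension adds all supergraph descendants of the rep", {
  g <- parse_obo(nucleus_obo())
  # seed only part of the branch: N:4 and N:7 missing from the keyword "nucleo"
  sp <- category_spec("nuc", keywords = "nucleus")
  sg <- seed_subgraph(g, sp)                      # seeds N:1 and decoy X:2
  expect_setequal(sg$seeded_ids, c("N:1", "X:2"))
  sg <- extend_comprehensive(g, sg)
  expect_setequal(sg$node_ids,
                  c("N:1", "N:2", "N:3", "N:4", "N:6", "N:7", "X:2"))
  sg <- constrain_to_representative(sg)
  expect_setequal(sg$member_ids, c("N:1", "N:2", "N:3", "N:4", "N:6", "N:7"))
  expect_equal(sg$removed_seed_ids, "X:2")
})

test_that("conservative extension adds only intermediates on leaf paths", {
  # rep -> mid -> leaf with mid unseeded; side is a descendant of rep on no
  # leaf path and must NOT be added
  obo <- c("[Term]", "id: R:1", "name: widget root", "",
           "[Term]", "id: R:2", "name: middle piece", "is_a: R:1", "",
           "[Term]", "id: R:3", "name: widget leaf", "is_a: R:2", "",
           "[Term]", "id: R:4", "name: side piece", "is_a: R:1", "")
  g <- parse_obo(obo)
  sp <- category_spec("w", keywords = "widget", extension_mode = "conservative")
  sg <- seed_subgraph(g, sp)
  expect_setequal(sg$seeded_ids, c("R:1", "R:3"))
  ext <- extend_conservative(g, sg)
  expect_setequal(ext$node_ids, c("R:1", "R:2", "R:3"))
  done <- constrain_to_representative(ext)
  expect_setequal(done$member_ids, c("R:1", "R:2", "R:3"))
  # fully-seeded paths add nothing
  sp2 <- category_spec("m", keywords = c("middle", "widget"),
                       extension_mode = "conservative")
  sg2 <- seed_subgraph(g, sp2)
  expect_equal(extend_conservative(g, sg2)$node_ids, sg2$node_ids)
})

test_that("constraint removes disconnected seeded components entirely", {
  obo <- c("[Term]", "id: S:1", "name: star hub", "",
           "[Term]", "id: S:2", "name: star arm", "is_a: S:1", "",
           "[Term]", "id: S:8", "name: lone star", "",
           "[Term]", "id: S:9", "name: star stray", "is_a: S:8", "")
  g <- parse_obo(obo)
  sg <- build_category(g, category_spec("star", keywords = "star"))
  # S:1 wins (2 descendants vs 1); the S:8/S:9 component is removed
  expect_equal(sg$representative_ids, "S:1")
  expect_setequal(sg$member_ids, c("S:1", "S:2"))
  expect_setequal(sg$removed_seed_ids, c("S:8", "S:9"))
})

test_that("an isolated keyword term forms a one-node category", {
  obo <- c(nucleus_obo(),
           "[Term]", "id: A:1", "name: aggresome", "is_a: N:0", "")
  g <- parse_obo(obo)
  sg <- build_category(g, category_spec("agg", keywords = "aggresome"))
  expect_equal(sg$representative_ids, "A:1")
  expect_equal(sg$member_ids, "A:1")
  ex <- subgraph_export(sg)
  expect_equal(ex$seeded_count, 1)
  expect_equal(ex$added_count, 0)
  expect_equal(ex$removed_count, 0)
  expect_equal(ex$total_count, 1)
})

test_that("seeded/added/removed accounting mirrors the bacterial-style pattern", {
  # many decoy seeds, few rooted: removed = seeded - rooted, plus extension
  fx <- generate_ontology(fixture_spec(n_categories = 2, depth = 2,
                                       branching = 2, has_part_fraction = 0,
                                       decoy_terms = 6, rng_seed = 42))
  g <- parse_obo(fx$obo)
  gt <- fx$ground_truth[[1]]
  sg <- build_category(g, category_spec(gt$keyword, keywords = gt$keyword))
  ex <- subgraph_export(sg)
  expect_equal(ex$seeded_count, length(gt$seeded))
  expect_equal(ex$removed_count, length(gt$removed))
  expect_equal(ex$total_count, length(gt$members))
  expect_equal(ex$seeded_count - ex$removed_count + ex$added_count,
               ex$total_count)
})

test_that("explicit seed terms skip election and act as representatives", {
  g <- parse_obo(nucleus_obo())
  sg <- build_category(g, category_spec("whole", seed_terms = "N:0"))
  expect_equal(sg$representative_ids, "N:0")
  expect_setequal(sg$member_ids, c("N:0", descendants(g, "N:0")))
  # multiple seed terms: union of the constrained subgraphs
  sg2 <- build_category(g, category_spec("two", seed_terms = c("N:2", "N:6")))
  expect_setequal(sg2$member_ids, c("N:2", "N:4", "N:6", "N:7"))
  expect_setequal(names(sg2$members_by_rep), c("N:2", "N:6"))
})

test_that("final members always equal rep plus within-subgraph descendants", {
  for (seed in c(3, 9)) {
    fx <- generate_ontology(fixture_spec(n_categories = 3, depth = 3,
                                         has_part_fraction = 0.2,
                                         cross_links = 2, decoy_terms = 5,
                                         rng_seed = seed))
    g <- parse_obo(fx$obo)
    for (gt in fx$ground_truth) {
      sg <- build_category(g, category_spec(gt$keyword, keywords = gt$keyword))
      inside <- sort(unique(c(sg$representative_ids,
                              unlist(lapply(sg$representative_ids, function(r)
                                c(r, goslicer:::local_closure(sg$children, r)))))),
                     method = "radix")
      expect_identical(sg$member_ids, inside)
      expect_length(intersect(sg$removed_seed_ids, sg$member_ids), 0)
      expect_setequal(union(sg$removed_seed_ids,
                            intersect(sg$seeded_ids, sg$member_ids)),
                      sg$seeded_ids)
    }
  }
})

test_that("conservative members are a subset of comprehensive members", {
  for (seed in c(7, 21)) {
    fx <- generate_ontology(fixture_spec(n_categories = 3, depth = 3,
                                         has_part_fraction = 0.25,
                                         cross_links = 3, decoy_terms = 4,
                                         rng_seed = seed))
    g <- parse_obo(fx$obo)
    for (gt in fx$ground_truth) {
      comp <- build_category(g, category_spec(gt$keyword, keywords = gt$keyword,
                                              extension_mode = "comprehensive"))
      cons <- build_category(g, category_spec(gt$keyword, keywords = gt$keyword,
                                              extension_mode = "conservative"))
      expect_true(all(cons$member_ids %in% comp$member_ids))
    }
  }
})

test_that("excluding has_part never grows a subgraph (same representative)", {
  fx <- generate_ontology(fixture_spec(n_categories = 3, depth = 3,
                                       has_part_fraction = 0.3, rng_seed = 13))
  g_full <- parse_obo(fx$obo)
  g_basic <- parse_obo(fx$obo, allowed_relations = c("is_a", "part_of"))
  for (gt in fx$ground_truth) {
    full <- build_category(g_full, category_spec(gt$keyword, keywords = gt$keyword))
    basic <- build_category(g_basic, category_spec(gt$keyword, keywords = gt$keyword))
    if (identical(full$representative_ids, basic$representative_ids)) {
      expect_true(all(basic$member_ids %in% full$member_ids))
    }
  }
})

test_that("building the same category twice is identical", {
  fx <- generate_ontology(fixture_spec(rng_seed = 2))
  g <- parse_obo(fx$obo)
  kw <- fx$ground_truth[[1]]$keyword
  a <- build_category(g, category_spec(kw, keywords = kw))
  b <- build_category(g, category_spec(kw, keywords = kw))
  expect_identical(a$member_ids, b$member_ids)
  expect_identical(a$representative_ids, b$representative_ids)
  expect_identical(a$removed_seed_ids, b$removed_seed_ids)
})
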