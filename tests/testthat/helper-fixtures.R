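# Shared fixtures built in code.

# Seven-term ontology exercising all three scoping relations:
#   B is_a A, C part_of A, A has_part D (inverted: D child of A),
#   E is_a B, F is_a C, G is_a D
seven_term_obo <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: A", "name: alpha assembly",
    "namespace: cellular_component",
    "def: \"the broadest fixture term\" []",
    "relationship: has_part D", "",
    "[Term]", "id: B", "name: beta alpha part",
    "namespace: cellular_component", "is_a: A", "",
    "[Term]", "id: C", "name: gamma piece",
    "namespace: cellular_component", "relationship: part_of A", "",
    "[Term]", "id: D", "name: delta module",
    "namespace: cellular_component", "",
    "[Term]", "id: E", "name: eps unit",
    "namespace: cellular_component", "is_a: B", "",
    "[Term]", "id: F", "name: zeta unit",
    "namespace: cellular_component", "is_a: C", "",
    "[Term]", "id: G", "name: eta unit",
    "namespace: cellular_component", "is_a: D", "")
}

# Random layered DAG as OBO text: node i may take parents among 1..(i-1),
# each edge drawn as is_a, part_of, or has_part.  Returns the text plus the
# oriented parent->child edge list (orientation applied by construction).
random_dag_obo <- function(n, seed, p_edge = 0.08, has_part_fraction = 0.3) {
  set.seed(seed)
  ids <- sprintf("N:%04d", seq_len(n))
  parent <- character(); child <- character(); rel <- character()
  for (i in 2:n) {
    k <- max(1L, stats::rbinom(1, min(i - 1L, 4L), p_edge * 5))
    ps <- sample(seq_len(i - 1L), min(k, i - 1L))
    for (p in ps) {
      r <- if (stats::runif(1) < has_part_fraction) "has_part"
           else sample(c("is_a", "part_of"), 1)
      parent <- c(parent, ids[p]); child <- c(child, ids[i]); rel <- c(rel, r)
    }
  }
  lines <- character()
  for (i in seq_len(n)) {
    stanza <- c("[Term]", paste0("id: ", ids[i]), paste0("name: node ", i))
    up <- which(child == ids[i] & rel != "has_part")
    for (e in up) {
      stanza <- c(stanza,
                  if (rel[e] == "is_a") paste0("is_a: ", parent[e])
                  else paste0("relationship: part_of ", parent[e]))
    }
    down <- which(parent == ids[i] & rel == "has_part")
    for (e in down) stanza <- c(stanza, paste0("relationship: has_part ", child[e]))
    lines <- c(lines, stanza, "")
  }
  list(obo = lines, ids = ids,
       edges = data.frame(parent = parent, child = child, relation = rel,
                          stringsAsFactors = FALSE))
}

# Independent transitive-closure oracle over an oriented parent->child edge
# list, via igraph reachability.
igraph_closure <- function(edges, ids) {
  g <- igraph::graph_from_data_frame(edges[, c("parent", "child")],
                                     vertices = ids, directed = TRUE)
  desc <- lapply(ids, function(v) {
    out <- names(igraph::subcomponent(g, v, mode = "out"))
    sort(setdiff(out, v), method = "radix")
  })
  anc <- lapply(ids, function(v) {
    out <- names(igraph::subcomponent(g, v, mode = "in"))
    sort(setdiff(out, v), method = "radix")
  })
  names(desc) <- names(anc) <- ids
  list(descendants = desc, ancestors = anc)
}

# A toy 17-column GAF record line.
gaf_record <- function(symbol, go_id, evidence = "EXP", db = "FIX",
                       qualifier = "") {
  paste(db, paste0(db, ":", symbol), symbol, qualifier, go_id,
        paste0(db, ":0000001"), evidence, "", "C", "toy gene product", "",
        "protein", "taxon:9606", "20160112", db, "", "", sep = "\t")
}
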