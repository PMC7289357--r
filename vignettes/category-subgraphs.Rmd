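---
title: "Scope-aware category subgraphs from the Gene Ontology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scope-aware category subgraphs from the Gene Ontology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goslicer)
```

## The model

The Gene Ontology is a directed acyclic graph whose edges carry relation
types with *different semantic orientations*. `is_a` and `part_of` always
point from a narrower term to a broader one, so transitive traversal along
them aggregates detail into generality. `has_part` does the opposite: the
subject is the broader term ("nucleus has_part nuclear membrane"), so a
traversal that treats it like the others walks out of the concept being
aggregated and produces wrong category assignments. That is why go-basic,
the GO release most mapping tools recommend, simply deletes `has_part` —
at the cost of discarding the term relationships it encodes.

`goslicer` instead annotates every relation with a scope orientation:

* `subject_narrower` — `is_a`, `part_of`: the subject is the child.
* `subject_broader` — `has_part`: the edge is inverted, the *object*
  becomes the child. The reading is mereological: "A has_part B" is taken
  as "B is part of *some* A" (not that every B occurs in an A, and not
  that A is exclusively composed of B). It is a scoping statement only.
* `non_scoping` — anything else (e.g. the regulates family): stored
  inert, contributing nothing to parent/child sets.

Because every scoping edge then runs narrower → broader, the graph remains
a DAG (the parser verifies acyclicity and rejects offending input naming a
cycle), and ancestors/descendants are plain transitive closures over the
oriented edges. Closures are computed lazily on first access, memoised,
and the whole cache is dropped whenever an edge is added or removed —
coarse, but mutation after parsing is rare, and correctness is easy to
audit.

## Category construction

A category is a keyword list (and/or explicit seed terms) plus an
extension mode. The pipeline runs each stage once, in order:

1. **Seeding.** Every term whose name *or definition* contains a keyword
   as a case-insensitive plain substring is seeded. No word-boundary
   logic is applied: substring semantics is the documented matching rule,
   and adding boundary logic would silently change seeded counts.
   Synonyms are deliberately not queried — GO synonym coverage is uneven
   across branches and synonym scopes (exact/narrow/broad/related) would
   weight terms unequally.
2. **Edge recreation.** The supergraph's scoping edges with both
   endpoints seeded are reproduced in the subgraph; subgraph nodes wrap
   supergraph nodes by id and never mutate them.
3. **Representative election.** Candidates are seeded terms with a
   keyword in the *name* (a definition hit seeds a term but cannot make
   it a category root). The candidate with the most within-subgraph
   descendants wins. Two open points were settled as follows:
   * *Leaves are admissible candidates.* A non-leaf always outranks a
     leaf on descendant count, so this matters only for categories whose
     concept is a single isolated term (an "aggresome"-style category of
     one node, which must root to itself rather than fail).
   * *Ties break to the lexicographically smallest id.* Descendant
     counts can tie; determinism requires a total order, and term ids are
     the only stable key.
4. **Extension.** Keyword seeding misses highly specific descendants
   whose names and definitions avoid the keyword. *Comprehensive*
   (default) adds every supergraph descendant of the representative.
   *Conservative* adds only supergraph terms on paths between existing
   subgraph leaves and the representative
   (`intersect(ancestors(leaf), descendants(representative))`), i.e. it
   completes paths without importing whole unseen branches. Comprehensive
   output always contains conservative output on the same input.
5. **Constraint.** Members become the representative plus its
   within-subgraph descendants. Seeded terms not rooted there — decoy
   matches such as a definition that merely mentions the keyword — are
   moved to `removed_seed_ids` and reported, which makes the
   seeded/added/removed/total accounting of a run auditable.

The representative search runs before extension (stage order is fixed);
extension is not iterated to a fixed point after constraint. Both choices
keep the pipeline a single deterministic pass — re-running a spec on the
same graph is bit-identical, and serialized outputs sort ids
lexicographically.

When a spec lists several seed terms, each becomes a representative, the
constrained subgraphs are built per representative, and the category's
member set is their union.

## Annotation mapping

Mapping tables associate each member term with its category root(s). With
several categories, nesting is resolved by *superset suppression*: if the
representative of category `c1` is itself a member of `c2`'s subgraph,
terms shared by both map only to the nearer root `c1`. The test is applied
at table-build time (representative membership), not per record, and a
representative always maps to its own category. Overlapping but non-nested
categories keep both mappings; `map_supersets = TRUE` disables suppression
entirely.

GAF 2.x rewriting is line-based: 17 tab-separated columns, `!` headers
passed through unchanged, one output row per (record, category) pair so no
category assignment is lost for downstream counting, unmapped records
preserved verbatim as an audit list, and an opt-in evidence-code filter
(with an IEA preset, the evidence class usually considered least
reliable). Qualifier-column semantics (including `NOT`) are ignored for
mapping — a known limitation, documented rather than guessed at. Record
conservation holds by construction: mapped + unmapped + evidence-dropped
= input records.

## Comparison metrics

Two subgraphs (or two per-gene annotation sets) are compared with:

* the **inclusion index** `I = |S_n ∩ S_g| / |S_n|`, where `S_n` is the
  non-reference set — callers must label which input is which, since the
  index is asymmetric;
* the **Jaccard index** `|∩| / |∪|`; under strict containment
  (`S_n ⊆ S_g`) `I = 1` and Jaccard reduces to `|S_n| / |S_g|`;
* a five-way per-gene **agreement classification** of an experimental
  source against a knowledgebase source: `no_annotation` (gene absent
  from the knowledgebase), `complete` (equal sets), `partial_superset`
  (knowledgebase strictly contains experimental), `partial` (some other
  overlap), `none` (disjoint). The classes are mutually exclusive and
  exhaustive, so counts partition the gene list. Per-category involvement
  counts tally category *incidences* within each class — a gene with two
  experimental locations contributes twice — so location sums exceed gene
  counts by design.

A generic-remapping helper coarsens category sets (e.g. folding
"centrosome" into "cytoskeleton") to reconcile granularity differences
between sources; remapping both sources with the same map can only grow
the complete-agreement count. Indices are serialized to six significant
figures.

The UniProt subcellular-location controlled vocabulary is parsed from its
line-prefixed flat file (`ID`/`AC`/`HI`/`HP`/`GO`/`//`; the prefixes are
configurable) into the same mapping-table shape: parentless terms are
category roots, each root maps to the GO cross-references of its recursive
children, and xref-less terms are traversed for connectivity but excluded
from the output.

## The synthetic-data generator

Real GO releases are large downloads; the package instead validates
against generated ontologies whose ground truth is known *by
construction* — membership is computed by direct reachability over the
generated edge list, never by the categorizer under test. A fixture
plants:

* keyword-named category branches (`depth` levels, `branching` children),
  each edge drawn as `is_a`/`part_of` or, with probability
  `has_part_fraction`, serialized as `parent has_part child`;
* optional inter-category `part_of` links, always from a higher-index
  branch into a lower-index one so the layered graph stays acyclic;
* decoy terms that mention keywords only in their definitions and hang
  off a separate shelf — seeded by construction, removed at constraint.

Defaults (3 categories, depth 3, branching 2, `has_part_fraction` 0.15,
4 decoys) give ~50-term ontologies: large enough to exercise multi-level
closures, mixed relations and decoy removal, small enough that the whole
suite runs in seconds. Toy GAF generation annotates genes to known member
terms and corrupts exactly `floor(noise × records)` GO ids to unmappable
values, so unmapped counts are predictable exactly.

What the fixtures do *not* emulate: realistic term-name text (names embed
keywords as clean tokens, so seeding precision is higher than on real GO
prose), synonym structure, obsolete-term churn, alt_id aliasing, and the
scale of real GO (tens of thousands of terms). Passing tests therefore
demonstrate correctness of the graph semantics and pipeline accounting,
not keyword-choice quality on real ontologies — keyword curation remains
the user's scientific responsibility.

## Numerical and degenerate-input choices

* Closure outputs are sets; any serialized order is lexicographic.
* Empty ontology input parses to an empty graph; unknown term lookups,
  empty keyword lists, empty mapping tables, and empty non-reference sets
  in the inclusion index are errors with classed conditions
  (`goslicer_domain_error` vs `goslicer_io_error`), which the CLI maps to
  exit codes 1 and 2.
* Obsolete terms are parsed but excluded from the node index — they
  cannot participate in categorization. alt_id merging is not performed
  (the ids do not occur in mapped outputs); unknown relations are kept
  inert with a one-time warning rather than dropped, so their presence is
  visible in the edge histogram.
* Cycle detection runs once after parsing (Kahn's algorithm); the error
  names one offending cycle.

## Validation scales

Closure correctness is checked against an independent igraph reachability
oracle on random 200–500-node multi-relation DAGs; the has_part-inversion
equivalence (a graph with `X has_part Y` is closure-identical to the same
graph with `Y part_of X`) on 120-node random DAGs; pipeline properties
(conservative ⊆ comprehensive, member-set invariant, exact ground-truth
recovery with decoy removal, GAF record conservation and planted-noise
recovery) on the default-scale fixtures across several seeds. These sizes
were chosen as the smallest that exercise every structural feature several
times over; all results are deterministic given the stated seeds.

## Known limitations

* Only `is_a`, `part_of`, `has_part` participate in scoping; the
  regulates family is stored inert rather than traversed.
* Keyword matching is substring-based by design; short keywords can
  over-seed (the constraint stage removes unrooted matches, but a decoy
  that *is* a descendant of the representative stays).
* GAF qualifier semantics (`NOT`) are ignored.
* Gene symbols are matched case-sensitively across sources.
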