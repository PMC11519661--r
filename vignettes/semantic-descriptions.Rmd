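---
title: "Ontology-anchored species descriptions with phenoscribe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-anchored species descriptions with phenoscribe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Traditional species descriptions are prose: precise to a trained reader,
opaque to a computer. The entity–quality (EQ) approach instead writes a
description as an ordered list of small, formal statements — an anatomical
*entity* (drawn from an anatomy ontology such as the insect skeletomuscular
anatomy ontology, AISM, or the beetle anatomy ontology, COLAO) *bears* a
*quality* (drawn from a quality ontology in the PATO style). Such statements
can be compiled to an RDF graph and queried with semantic tools, while a
deterministic renderer produces the clause-style text a taxonomist reads.

phenoscribe implements that whole toolchain for the model system of the
Malagasy *Scarabaeus* dung beetles: a term registry with identifier minting,
a parser for a Phenoscript-style description language, a graph compiler, a
natural-language renderer, a statement-level differ (the machinery of a
diagnosis), a dichotomous-key engine, a Darwin Core occurrence-record reader,
and a nanopublication assembler. The bundled fixtures are full transcriptions
of the published male descriptions of *Scarabaeus sakalava* and
*S. viettei*, their type-series records, and the identification key to adult
Malagasy *Scarabaeus*.

```{r setup}
library(phenoscribe)
```

## The description language

The package reads a small domain-specific language (phs). The published
treatments print only fragments of the original language, so the grammar
implemented here is a documented dialect, fixed as follows:

* one statement per `;`, comments from `#` to end of line;
* `@key value` metadata lines (catalog number, role-in-modeling, denotes,
  taxon id, parent name usage id) precede the phenotype statements, plus
  `@taxon` and free-text `@note` annotations (sexual dimorphism, variation)
  that the toolchain carries as opaque text;
* entity paths chain terms with `>`; the link is implicit part-of;
* a path step may group sibling terms, e.g. the antennal club built from
  three flagellomeres:
  `aism-antenna_with_9_antennomeres > colao-antennal_club >
  (aism-flagellomere_5, aism-flagellomere_6, aism-flagellomere_7)`.
  Statement-level groupings expand to one statement per leaf, matching the
  clause-per-leaf style of the published text;
* `path : pato-quality ;` asserts a quality; `path .ro-relation path ;`
  asserts a relation (homology, adjacency, encircles, coincident-with), with
  an optional attached quality on the object;
* `path : width larger_than length of path ;` is a comparative statement —
  the comparator set is closed to the two forms attested in the treatments
  (`larger_than`, `similar_in_magnitude_relative_to`), and anything else is
  a syntax error, so dialect drift fails loudly;
* `path : length = 23.0 uo-millimeter ;` is a measurement; the verbatim
  decimal text is preserved so that `23.0` never silently becomes `23`;
* `path { ... }` opens a block: nested subjects are resolved against the
  block path, and a statement starting with `:` or `.` applies to the block
  subject itself. The published blocks restate context headers
  ("pronotum, dorsal region: convex; pronotum, lateral margin: curved");
  block scoping reproduces that structure without repetition, and the parser
  expands every subject to its fully qualified path.

Two design points deserve a note. First, relational objects and comparative
references are stored *as authored*, not block-qualified: the published
reference texts show arbitrary-depth suffixes of the full path ("length of
pronotum", but also "elytral stria 7 of male organism"), so only the authored
steps can reproduce them. Second, the parser also accepts the renderer's own
label-form output (paths as `", "`-joined registry labels, relations spelled
with spaces, references reversed and `" of "`-joined). That makes
parse → render → parse a fixpoint, which is the property that guarantees the
human-readable file and the semantic file carry identical information.

```{r parse}
reg <- seed_registry()
sak <- example_description("sakalava", reg)
sak
extract_measurements(sak, reg)
```

## Rendering

Rendering is deterministic and clause-per-statement: registry labels joined
with `", "`, qualities after `": "`, one clause per line, every clause closed
by `";"`. Labels come from the registry (so `antenna_with_9_antennomeres`
prints as "antenna with 9 antennomeres" and hyphenated labels like
"chitin-based cuticle" survive). No sentence aggregation or pronoun handling
is attempted — the published style is itself clause-per-statement, and a pure
function of the statement list keeps the rendering reproducible.

```{r render}
r <- render_description(sak, reg)
r$clauses[c(1, 6, 44, 119)]
```

## The term registry

The registry maps `(PREFIX, local_name)` pairs to terms with labels and
optional zero-padded 7-digit identifiers, and holds the relation vocabulary
and a symmetric homology store (used to record that the non-articulated
tibial spines of these beetles are homologous with the tibial spurs of
relatives). IRIs follow the OBO convention
`<base><PREFIX>_<id-or-local-name>`. The seeded vocabulary ships exactly the
terms used by the two transcribed descriptions plus internal predicates; it
is a local fixture, not a download, so the whole package runs offline. The
identifier block 0000413–0000437 minted for these descriptions is recreated
with `mint_range()`; the source treatments do not print the 25 labels, so
minting defaults to placeholder labels.

The predicate IRIs for has-quality, denotes, catalog-number and kin are not
printed anywhere in the source treatments; they are pinned as placeholder
IRIs under the internal `PHEN` namespace so that output is deterministic.

## Graph compilation

`compile_description()` produces an instance-based EQ graph: every distinct
canonical entity path gets exactly one skolem-IRI instance node (a bijection,
asserted in tests), typed by its ontology class, labelled, and linked to its
parent path with part-of. Qualities are instance nodes linked from their
bearer; comparisons and measurements are reified nodes; metadata hangs off a
description node (the catalog number is kept a literal; taxon and parent
name usage identifiers become IRI links). Skolem IRIs derived from canonical
paths mean no blank nodes: serialization is byte-stable, and graph
isomorphism reduces to set equality of triples.

```{r compile}
g <- compile_description(sak, reg)
g
cat(substr(serialize_graph(g, "turtle"), 1, 300))
```

Turtle, N-Triples and TriG are written and read by the package itself (no
RDF library exists in the R dependency stack used here); the reader covers
the standard-conformant subset the writers emit, and the writers are
cross-checked against an independent RDF library in the test suite.

## Diagnosis by diffing

`diff_descriptions()` matches statements by canonical subject path and
statement kind. Qualities of a shared subject are compared as multisets;
leftovers on both sides are paired in authored order into `changed`
(realizing a term-wise comparison for subjects bearing several qualities,
such as the anterolateral pronotal angle: *sharp* matches, *lateral
orientation* vs *oblique orientation* pairs as changed). A subject present in
only one description — such as the extra "dorsal region" level under the gena
and clypeus of *S. viettei* — is a structural difference and lands in
`only_in_*` rather than being fuzzily aligned. Measurements are compared
numerically. Whether that nested-path discrepancy is biological or a
transcription artifact of the source files cannot be decided from the
published text; the differ reports it either way.

```{r diff}
vie <- example_description("viettei", reg)
d <- diff_descriptions(sak, vie, reg)
d
summarize_diagnosis(d)[3:4]
```

## Keys, occurrences, nanopublications

The dichotomous key engine stores couplets of exactly two leads (in the
tabular layout of published keys, lead one is the numbered row, lead two the
dash row); lead text is deliberately opaque — linking lead wording to
description statements would need NLP and is out of scope. Validation checks
root presence, dangling targets, reachability and cycles; evaluation follows
a vector of 1/2 choices.

```{r key}
key <- example_key()
evaluate_key(key, c(2, 2, 1))
enumerate_taxa(key)
```

Occurrence records are read from `field: value` blocks transcribed from the
Materials sections, kept verbatim (printed coordinate precision is never
rounded), validated (counts, coordinate ranges, occurrence-id uniqueness) and
exported as Darwin Core CSV. The verbatim event dates on the labels mix at
least four shapes; a closed dialect table (`MM-YYYY`, `DD-MM-YYYY`,
`DD/DD-MM-YYYY`) is normalized to ISO-8601 and everything else — collector
annotations like "Peyrieras-III" — stays verbatim only.

```{r dwc}
occ <- example_occurrences("viettei")
summarize_occurrences(occ)[c("n_records", "total_individuals")]
normalize_event_date(c("12-2006", "03/07-03-2022", "Peyrieras-III"))
```

Nanopublications follow the head/assertion/provenance/pubinfo quartet with
fragment-suffixed graph URIs; creator and timestamp are explicit arguments,
so the TriG output of two identical calls is byte-identical.

## Numerical and degenerate-input choices

* Measurement values must be finite and positive; the verbatim decimal text
  is the unit of comparison in round trips, the parsed double in diffs.
* An empty source parses to an empty description, renders to an empty body,
  and compiles to an empty (prefix-only) document.
* Duplicate metadata keys are an error at parse time and an issue in
  `validate_description()`; duplicated identical statements are legal and
  diff positionally.
* Quality-node IRIs append a suffix on repeated (bearer, quality) pairs so
  the graph never silently merges repeated assertions.
* Deterministic ordering everywhere: triples sort lexicographically before
  serialization; diff buckets preserve first-encounter key order.

## What the fixtures do and do not show

The bundled phs files are this package's transcriptions of the two published
male descriptions into the dialect above: the clause inventory, statement
order, qualities, relations, comparatives, the two body lengths and all
metadata follow the published text, while the block structure is the
transcriber's (the original source files are not published, and whether the
original dialect uses block scoping or full paths per statement is unknown).
The reference clause files are maintained independently of the phs sources
and serve as the textual oracle: rendering must reproduce them
clause-for-clause, and the differ's buckets must equal their line-by-line
alignment. Passing those tests shows the toolchain is internally consistent
and faithful to the published text; it does not validate the grammar against
the original unpublished sources, and the registry's placeholder IRIs stand
in for ontology releases that are deliberately not fetched.

All bundled inputs are small (hundreds of statements, dozens of records), so
the full test suite and the acceptance script run in seconds on one CPU.
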