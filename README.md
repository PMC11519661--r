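# phenoscribe

Ontology-anchored, computable species descriptions in R — built around the
two semantically described Malagasy dung beetles, *Scarabaeus sakalava* and
*Scarabaeus viettei* (Coleoptera, Scarabaeinae).

Taxonomic descriptions written in prose are hard for machines to reuse.
phenoscribe implements the entity–quality (EQ) alternative end to end: a
description is an ordered list of formal statements in which an anatomical
**entity** (an AISM/COLAO-style ontology term, addressed by a part-of path
such as *male organism › pronotum › dorsal region*) bears a **quality** (a
PATO-style term such as *convex*), or stands in a relation (homology,
adjacency), a comparison (`width larger_than length`), or a measurement
(`length = 23.0 mm`). From that single source the package derives everything
else:

* **`parse_description()` / `read_phs()`** — parse the Phenoscript-style DSL
  into a `semantic_description` (ordered statements + opaque annotations),
  with term resolution against a seeded **term registry**
  (`seed_registry()`, `resolve_term()`, `mint_range()`, homology store);
* **`render_description()`** — deterministic clause-per-statement
  natural-language rendering (markdown or HTML); parse → render → parse is a
  fixpoint;
* **`compile_description()`** — typed RDF instance graph (skolem IRIs, no
  blank nodes) with Turtle / N-Triples / TriG writers and readers
  (`serialize_graph()`, `parse_rdf()`, `graph_isomorphic()`);
* **`diff_descriptions()` / `summarize_diagnosis()`** — statement-level
  differences between two species: the computable core of a taxonomic
  diagnosis;
* **`read_key()` / `evaluate_key()` / `enumerate_taxa()`** — dichotomous
  identification keys (fixture: the key to adult Malagasy *Scarabaeus*);
* **`parse_occurrences()` / `summarize_occurrences()` / `export_dwc_csv()`**
  — Darwin Core occurrence records transcribed from Materials blocks, with
  verbatim-preserving event-date normalization;
* **`build_taxon_nanopub()` / `build_habitat_nanopub()`** — nanopublications
  (head/assertion/provenance/pubinfo named graphs, serialized as TriG).

The complete transcribed male descriptions of both species, their type
series, the seeded vocabulary and the identification key ship as plain-text
fixtures under `inst/extdata/`.

## Worked example

```r
library(phenoscribe)

reg <- seed_registry()
sak <- example_description("sakalava", reg)
vie <- example_description("viettei", reg)

sak
#> <semantic_description> Scarabaeus sakalava: 119 statements
#>   (comparative=4, measurement=1, metadata=5, quality=100, relational=9)

extract_measurements(sak, reg)
#>            path attribute value       unit
#> 1 male organism    length    23 millimeter

d <- diff_descriptions(sak, vie, reg)
d
#> <description_diff> Scarabaeus sakalava vs Scarabaeus viettei
#>   changed: 4 | only in a: 3 | only in b: 3 | measurement deltas: 1

summarize_diagnosis(d)[3:4]
#> [1] "male organism / anterolateral pronotal angle: lateral orientation in
#>      Scarabaeus sakalava, oblique orientation in Scarabaeus viettei;"
#> [2] "male organism / parameres / distal region / dorsal margin: straight
#>      angle to in Scarabaeus sakalava, obtuse angle to in Scarabaeus viettei;"

evaluate_key(example_key(), c(2, 2, 1))
#> [1] "Scarabaeus sakalava"

summarize_occurrences(example_occurrences("viettei"))$total_individuals
#> [1] 31
```

The diff above *is* the published diagnosis: the two species differ in the
orientation of the anterolateral pronotal angle (lateral vs oblique), the
angle of the distal dorsal paramere margin (straight vs obtuse), an extra
"dorsal region" level under the gena and clypeus (reported as a structural
difference), body length (23.0 vs 21.5 mm), and their catalog/taxon
identifiers.

A thin command-line front end over the same functions lives at
`inst/scripts/phenoscribe.R`:

```sh
Rscript inst/scripts/phenoscribe.R render inst/extdata/scarabaeus_sakalava_male.phs
Rscript inst/scripts/phenoscribe.R key run inst/extdata/malagasy_scarabaeus_key.yml --choices 2,2,1
```

## Package layout

* `R/` — registry, DSL parser, renderer, RDF layer, graph compiler,
  nanopubs, differ, key engine, Darwin Core reader
* `inst/extdata/` — phs transcriptions, reference clause files, vocabulary,
  key, Materials records (all plain text)
* `vignettes/semantic-descriptions.Rmd` — the methods vignette: dialect
  definition, modeling decisions, limitations
* `tests/testthat/` — unit, property and end-to-end suites
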