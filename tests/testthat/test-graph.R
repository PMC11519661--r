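test_that("a one-statement description compiles to the fixed minimal shape", {
  reg <- fx_registry()
  d <- parse_description("aism-male_organism : pato-ovate ;", reg)
  g <- compile_description(d, reg)
  # organism type + organism label + quality type + bearer has-quality link
  expect_identical(n_triples(g), 4L)
  t <- g$triples
  organism <- node_table(g)[["male organism"]]
  expect_identical(sum(t$s == organism & t$p == phenoscribe:::RDF_TYPE), 1L)
  qnode <- t$o[t$s == organism & grepl("has_quality$", t$p)]
  expect_length(qnode, 1L)
  expect_match(t$o[t$s == qnode & t$p == phenoscribe:::RDF_TYPE], "PATO_ovate$")
})

test_that("metadata compiles onto the description node with the right term types", {
  g <- fx_graph("sakalava")
  t <- g$triples
  cat_row <- t[grepl("catalog_number$", t$p), ]
  expect_identical(cat_row$o, "http://id.luomus.fi/GZ.15827")
  expect_identical(cat_row$o_kind, "literal")
  parent_row <- t[grepl("parent_name_usage_id$", t$p), ]
  expect_identical(parent_row$o, "https://www.gbif.org/species/9074838")
  expect_identical(parent_row$o_kind, "iri")
})

test_that("the node table is a bijection over the distinct canonical paths", {
  reg <- fx_registry()
  for (sp in c("sakalava", "viettei")) {
    d <- fx_desc(sp)
    g <- fx_graph(sp)
    # independent enumeration from the parsed statement list: subjects,
    # objects and references plus all their ancestor prefixes
    paths <- character()
    for (s in d$statements) {
      for (field in c("subject", "object", "reference")) {
        tokens <- s[[field]]
        if (is.null(tokens)) next
        for (k in seq_along(tokens)) {
          paths <- c(paths, canonical_path(tokens[1:k], reg))
        }
      }
    }
    paths <- unique(paths)
    nt <- node_table(g)
    expect_setequal(names(nt), paths)
    expect_identical(anyDuplicated(unname(nt)), 0L)
  }
})

test_that("compiled graphs round-trip through every dialect", {
  for (sp in c("sakalava", "viettei")) {
    g <- fx_graph(sp)
    plain <- structure(list(triples = g$triples, prefixes = g$prefixes),
                       class = "rdf_graph")
    for (dia in c("turtle", "ntriples", "trig")) {
      txt <- serialize_graph(g, dia)
      expect_identical(txt, serialize_graph(g, dia))
      expect_true(graph_isomorphic(plain, parse_rdf(txt, dia)),
                  info = paste(sp, dia))
    }
  }
})

test_that("compilation refuses a description that does not validate", {
  reg <- fx_registry()
  bad <- semantic_description(statements = list(
    quality_statement("aism-made_up_part", "pato-convex")))
  expect_error(compile_description(bad, reg),
               class = "phenoscribe_validation_failed")
})

test_that("taxon nanopubs carry the name assertion in the four-graph layout", {
  reg <- fx_registry()
  np <- build_taxon_nanopub("Scarabaeus sakalava", "Montanaro & Tarasov",
                            rank = "species",
                            parent_usage = "https://www.gbif.org/species/9074838",
                            timestamp = "2024-10-21T00:00:00Z",
                            registry = reg)
  a <- nanopub_graph(np, "assertion")
  expect_true("Scarabaeus sakalava" %in% a$o)
  expect_true("https://www.gbif.org/species/9074838" %in% a$o)
  head_g <- nanopub_graph(np, "head")
  expect_setequal(
    head_g$o[grepl("has(Assertion|Provenance|PublicationInfo)$", head_g$p)],
    paste0(np$uri, c("#assertion", "#provenance", "#pubinfo")))
  expect_identical(nrow(nanopub_graph(np, "pubinfo")), 2L)

  expect_error(build_taxon_nanopub("", "Montanaro & Tarasov", registry = reg),
               class = "phenoscribe_missing_field")

  np2 <- build_taxon_nanopub("Scarabaeus sakalava", "Montanaro & Tarasov",
                             rank = "species",
                             parent_usage = "https://www.gbif.org/species/9074838",
                             timestamp = "2024-10-21T00:00:00Z",
                             registry = reg)
  expect_identical(serialize_nanopub(np), serialize_nanopub(np2))

  quads <- parse_rdf(serialize_nanopub(np), "trig")
  expect_setequal(unique(quads$triples$graph),
                  paste0(np$uri, c("#Head", "#assertion", "#provenance", "#pubinfo")))
})

test_that("habitat nanopubs assert the dry-deciduous-forest association", {
  reg <- fx_registry()
  for (taxon in c("Scarabaeus sakalava", "Scarabaeus viettei")) {
    np <- build_habitat_nanopub(taxon, "dry deciduous forest",
                                timestamp = "2024-10-21T00:00:00Z",
                                registry = reg)
    a <- nanopub_graph(np, "assertion")
    expect_true("dry deciduous forest" %in% a$o)
    expect_true(taxon %in% a$o)
  }
  expect_error(build_habitat_nanopub("Scarabaeus viettei", "", registry = reg),
               class = "phenoscribe_missing_field")
})
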