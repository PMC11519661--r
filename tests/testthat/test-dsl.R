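test_that("a grouped antennal-club path parses into a grouping step", {
  reg <- fx_registry()
  p <- parse_entity_path(
    "aism-antenna_with_9_antennomeres > colao-antennal_club > (aism-flagellomere_5, aism-flagellomere_6, aism-flagellomere_7)",
    reg)
  expect_length(p$steps, 3L)
  expect_identical(p$steps[[3]],
                   c("aism-flagellomere_5", "aism-flagellomere_6", "aism-flagellomere_7"))
  keys <- canonical_path(p, reg)
  expect_identical(keys, c(
    "antenna with 9 antennomeres / antennal club / flagellomere 5",
    "antenna with 9 antennomeres / antennal club / flagellomere 6",
    "antenna with 9 antennomeres / antennal club / flagellomere 7"))
})

test_that("grouped statements expand to one statement per leaf, in order", {
  reg <- fx_registry()
  d <- parse_description(
    "colao-antennal_club > (aism-flagellomere_5, aism-flagellomere_6) : pato-present ;",
    reg)
  expect_length(d$statements, 2L)
  expect_identical(d$statements[[1]]$subject,
                   c("colao-antennal_club", "aism-flagellomere_5"))
  expect_identical(d$statements[[2]]$subject,
                   c("colao-antennal_club", "aism-flagellomere_6"))
})

test_that("empty source yields an empty description", {
  d <- parse_description("", fx_registry())
  expect_length(d$statements, 0L)
  expect_identical(d$taxon_label, "")
})

test_that("the transcribed descriptions parse with one statement per published clause", {
  for (sp in c("sakalava", "viettei")) {
    d <- fx_desc(sp)
    # clause-count oracle: the reference transcription holds the
    # ";"-delimited clauses of the published block, one per line
    expect_length(d$statements, length(reference_clauses(sp)))
  }
})

test_that("statement order is preserved and parsing is deterministic", {
  reg <- fx_registry()
  d1 <- fx_desc("sakalava")
  d2 <- example_description("sakalava", reg)
  expect_identical(signatures(d1), signatures(d2))
  kinds <- vapply(d1$statements, phenoscribe:::statement_kind, character(1))
  expect_identical(unique(kinds[1:5]), "metadata")
})

test_that("organism-level measurements are extracted in order", {
  reg <- fx_registry()
  ms <- extract_measurements(fx_desc("sakalava"), reg)
  expect_identical(nrow(ms), 1L)
  expect_identical(ms$path, "male organism")
  expect_identical(ms$attribute, "length")
  expect_equal(ms$value, 23.0)
  expect_identical(ms$unit, "millimeter")

  mv <- extract_measurements(fx_desc("viettei"), reg)
  expect_equal(mv$value, 21.5)

  none <- parse_description("aism-pronotum : pato-convex ;", reg)
  expect_identical(nrow(extract_measurements(none, reg)), 0L)
})

test_that("canonical path keys are deterministic and label-based", {
  reg <- fx_registry()
  tokens <- c("aism-male_organism", "aism-pronotum", "aism-dorsal_region")
  expect_identical(canonical_path(tokens, reg),
                   "male organism / pronotum / dorsal region")
  # same key regardless of parse route
  via_path <- parse_entity_path("aism-male_organism > aism-pronotum > aism-dorsal_region", reg)
  expect_identical(canonical_path(via_path, reg), canonical_path(tokens, reg))

  set.seed(7)
  toks <- names(Filter(function(t) !t$relation, reg$env$terms))
  toks <- vapply(reg$env$terms[toks], render_token, character(1))
  for (i in 1:25) {
    a <- sample(toks, sample(1:5, 1))
    b <- sample(toks, sample(1:5, 1))
    expect_identical(identical(canonical_path(a, reg), canonical_path(b, reg)),
                     identical(a, b))
  }
})

test_that("validation reports every issue without throwing", {
  reg <- fx_registry()
  expect_length(validate_description(fx_desc("sakalava"), reg), 0L)
  expect_length(validate_description(fx_desc("viettei"), reg), 0L)

  bad <- semantic_description(statements = list(
    quality_statement("aism-no_such_part", "pato-convex")))
  issues <- validate_description(bad, reg)
  expect_length(issues, 1L)
  expect_match(issues, "no_such_part")

  dup <- semantic_description(statements = list(
    metadata_statement("catalog_number", "http://id.luomus.fi/GZ.15827"),
    metadata_statement("catalog_number", "http://id.luomus.fi/GZ.15828")))
  issues <- validate_description(dup, reg)
  expect_length(issues, 1L)
  expect_match(issues, "duplicate")
})

test_that("syntax and resolution errors carry line numbers and classes", {
  reg <- fx_registry()
  expect_error(parse_description("aism-pronotum : pato-convex ;\naism-wat ;", reg),
               class = "phenoscribe_syntax")
  err <- tryCatch(parse_description("aism-pronotum : pato-convex ;\naism-bogus_part : pato-convex ;", reg),
                  error = identity)
  expect_s3_class(err, "phenoscribe_unknown_term")
  expect_match(conditionMessage(err), "line 2")
  expect_error(parse_description(
    "@catalog_number http://x.org/1\n@catalog_number http://x.org/2\n", reg),
    class = "phenoscribe_duplicate_metadata")
  expect_error(parse_description("aism-pronotum { : pato-convex ;", reg),
               class = "phenoscribe_syntax")
  # unknown comparators are syntax errors (closed comparator set)
  expect_error(parse_description(
    "aism-pronotum : width smaller_than length of aism-pronotum ;", reg),
    class = "phenoscribe_syntax")
})

test_that("relation and quality roles are enforced at parse time", {
  reg <- fx_registry()
  expect_error(parse_description("aism-pronotum : ro-encircles ;", reg),
               class = "phenoscribe_not_quality")
  expect_error(parse_description("aism-pronotum .pato-convex aism-vertex ;", reg),
               class = "phenoscribe_not_relation")
})

test_that("block scoping expands to fully qualified subject paths", {
  reg <- fx_registry()
  d <- parse_description(paste(
    "aism-male_organism {",
    "  aism-pronotum {",
    "    aism-dorsal_region : pato-convex ;",
    "    : pato-sharp ;",
    "  }",
    "}", sep = "\n"), reg)
  expect_identical(canonical_path(d$statements[[1]]$subject, reg),
                   "male organism / pronotum / dorsal region")
  expect_identical(canonical_path(d$statements[[2]]$subject, reg),
                   "male organism / pronotum")
})
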