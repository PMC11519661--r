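test_that("diffing a description against itself is empty in every bucket", {
  reg <- fx_registry()
  for (sp in c("sakalava", "viettei")) {
    d <- diff_descriptions(fx_desc(sp), fx_desc(sp), reg)
    expect_identical(nrow(d$only_in_a), 0L)
    expect_identical(nrow(d$only_in_b), 0L)
    expect_identical(nrow(d$changed), 0L)
    expect_identical(nrow(d$measurement_deltas), 0L)
    expect_length(summarize_diagnosis(d), 0L)
  }
})

test_that("the two treatments diff to the published diagnosis", {
  reg <- fx_registry()
  d <- diff_descriptions(fx_desc("sakalava"), fx_desc("viettei"), reg)

  ch <- d$changed
  angle <- ch[ch$path == "male organism / anterolateral pronotal angle", ]
  expect_identical(angle$value_a, "lateral orientation")
  expect_identical(angle$value_b, "oblique orientation")

  par <- ch[ch$path == "male organism / parameres / distal region / dorsal margin", ]
  expect_identical(par$value_a, "straight angle to")
  expect_identical(par$value_b, "obtuse angle to")

  md <- d$measurement_deltas
  expect_identical(md$path, "male organism")
  expect_equal(md$value_a, 23.0)
  expect_equal(md$value_b, 21.5)

  # the extra anatomical level under gena/clypeus is structural, not changed
  expect_setequal(d$only_in_a$path, c(
    "male organism / gena / medial region / granulated cuticle",
    "male organism / gena / lateral region",
    "male organism / clypeus / anterior region"))
  expect_setequal(d$only_in_b$path, c(
    "male organism / gena / dorsal region / medial region / granulated cuticle",
    "male organism / gena / dorsal region / lateral region",
    "male organism / clypeus / dorsal region / anterior region"))

  # metadata differences (catalog number, taxon id) are the only other changes
  expect_setequal(setdiff(ch$path, c(angle$path, par$path)),
                  c("catalog_number", "taxon_id"))
})

test_that("diff buckets equal an independent clause-by-clause alignment", {
  # textual oracle: align the two published clause transcriptions line by
  # line (both blocks have the same clause inventory) and collect the
  # positions where the printed text differs
  a_lines <- squish(reference_clauses("sakalava"))
  b_lines <- squish(reference_clauses("viettei"))
  expect_identical(length(a_lines), length(b_lines))
  differing <- which(a_lines != b_lines)

  reg <- fx_registry()
  d <- diff_descriptions(fx_desc("sakalava"), fx_desc("viettei"), reg)
  n_report <- nrow(d$changed) + nrow(d$measurement_deltas) +
    max(nrow(d$only_in_a), nrow(d$only_in_b))
  expect_identical(length(differing), n_report)

  # every changed value pair is visible verbatim in the aligned clause pair
  for (i in seq_len(nrow(d$changed))) {
    hit <- which(grepl(d$changed$value_a[i], a_lines, fixed = TRUE) &
                   grepl(d$changed$value_b[i], b_lines, fixed = TRUE) &
                   a_lines != b_lines)
    expect_gte(length(hit), 1L)
  }
  # structural entries correspond to aligned pairs whose paths differ
  for (i in seq_len(nrow(d$only_in_a))) {
    lhs <- gsub(" / ", ", ", d$only_in_a$path[i], fixed = TRUE)
    expect_true(any(startsWith(a_lines[differing], lhs)))
  }
  for (i in seq_len(nrow(d$only_in_b))) {
    lhs <- gsub(" / ", ", ", d$only_in_b$path[i], fixed = TRUE)
    expect_true(any(startsWith(b_lines[differing], lhs)))
  }
  expect_true(any(grepl("23.0", a_lines[differing], fixed = TRUE)))
  expect_true(any(grepl("21.5", b_lines[differing], fixed = TRUE)))
})

test_that("diff is symmetric with swapped buckets and values", {
  reg <- fx_registry()
  ab <- diff_descriptions(fx_desc("sakalava"), fx_desc("viettei"), reg)
  ba <- diff_descriptions(fx_desc("viettei"), fx_desc("sakalava"), reg)
  sort_df <- function(df) df[do.call(order, df), , drop = FALSE]
  expect_identical(sort_df(ab$only_in_a)$path, sort_df(ba$only_in_b)$path)
  expect_identical(sort_df(ab$only_in_b)$path, sort_df(ba$only_in_a)$path)
  expect_setequal(paste(ab$changed$path, ab$changed$value_a, ab$changed$value_b),
                  paste(ba$changed$path, ba$changed$value_b, ba$changed$value_a))
  expect_equal(ab$measurement_deltas$value_a, ba$measurement_deltas$value_b)
})

test_that("changed paths in a two-step diff appear in one of the single steps", {
  reg <- fx_registry()
  a <- fx_desc("sakalava")
  c_ <- fx_desc("viettei")
  # perturbed intermediate: sakalava with one quality flipped
  b <- a
  idx <- which(vapply(b$statements, function(s) {
    phenoscribe:::statement_kind(s) == "quality" &&
      identical(s$quality, "pato-concealed")
  }, logical(1)))
  b$statements[[idx]]$quality <- "pato-flattened"
  changed_paths <- function(x, y) {
    d <- diff_descriptions(x, y, reg)
    unique(c(d$changed$path, d$only_in_a$path, d$only_in_b$path,
             d$measurement_deltas$path))
  }
  ac <- changed_paths(a, c_)
  ab <- changed_paths(a, b)
  bc <- changed_paths(b, c_)
  expect_true(all(ac %in% union(ab, bc)))
  expect_true("male organism / scutellar shield" %in% ab)
})

test_that("duplicate statements within one description are diffed positionally", {
  reg <- fx_registry()
  twice <- parse_description(
    "aism-pronotum : pato-convex ;\naism-pronotum : pato-convex ;", reg)
  once <- parse_description("aism-pronotum : pato-convex ;", reg)
  d <- diff_descriptions(twice, once, reg)
  expect_identical(nrow(d$changed), 0L)
  expect_identical(nrow(d$only_in_a), 1L)
  expect_identical(d$only_in_a$value, "convex")
})

test_that("diagnosis lines cover every report entry and name the key character", {
  reg <- fx_registry()
  d <- diff_descriptions(fx_desc("sakalava"), fx_desc("viettei"), reg)
  lines <- summarize_diagnosis(d)
  expect_length(lines, nrow(d$changed) + nrow(d$only_in_a) + nrow(d$only_in_b) +
                  nrow(d$measurement_deltas))
  expect_true(any(grepl("anterolateral pronotal angle", lines)))
})

test_that("statement-level diffs correspond to the compiled triple differences", {
  reg <- fx_registry()
  ga <- fx_graph("sakalava")
  gb <- fx_graph("viettei")
  key <- function(g) do.call(paste, c(g$triples, sep = "\r"))
  sym <- c(setdiff(key(ga), key(gb)), setdiff(key(gb), key(ga)))
  expect_gt(length(sym), 0L)

  d <- diff_descriptions(fx_desc("sakalava"), fx_desc("viettei"), reg)
  slug_of <- function(path) {
    gsub(" ", "_", gsub(" / ", ".", gsub("-", "_", path)))
  }
  flagged_slugs <- c(
    # changed qualities differ in their quality instance nodes
    vapply(seq_len(nrow(d$changed)), function(i) {
      if (d$changed$kind[i] == "metadata") return(NA_character_)
      paste0(slug_of(d$changed$path[i]), "/q-")
    }, character(1)),
    vapply(d$only_in_a$path, slug_of, character(1)),
    vapply(d$only_in_b$path, slug_of, character(1)),
    # measurement deltas differ on the reified measurement node
    vapply(seq_len(nrow(d$measurement_deltas)), function(i) {
      paste0(slug_of(d$measurement_deltas$path[i]), "/m-",
             d$measurement_deltas$attribute[i])
    }, character(1))
  )
  flagged_slugs <- flagged_slugs[!is.na(flagged_slugs)]
  meta_preds <- c("catalog_number", "taxon_id")
  # nodes existing in only one compiled graph (intermediate levels of a
  # structural difference) are part of the structural explanation
  unique_nodes <- c(setdiff(node_table(ga), node_table(gb)),
                    setdiff(node_table(gb), node_table(ga)))
  explained <- vapply(sym, function(line) {
    any(vapply(flagged_slugs, function(s) grepl(s, line, fixed = TRUE), logical(1))) ||
      any(vapply(meta_preds, function(p) grepl(p, line, fixed = TRUE), logical(1))) ||
      any(vapply(unique_nodes, function(n) grepl(n, line, fixed = TRUE), logical(1)))
  }, logical(1))
  expect_true(all(explained))

  # and conversely every flagged non-metadata path touches some differing triple
  for (s in flagged_slugs) {
    expect_true(any(grepl(s, sym, fixed = TRUE)), info = s)
  }
})
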