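test_that("the type series parses with counts and coordinates as printed", {
  occ <- example_occurrences("sakalava")
  expect_identical(nrow(occ), 9L)
  expect_identical(sum(occ$typeStatus == "Holotype"), 1L)
  expect_identical(sum(occ$typeStatus == "Paratype"), 8L)

  holo <- occ[occ$typeStatus == "Holotype", ]
  expect_match(holo$catalogNumber, "GZ\\.15827$")
  expect_identical(holo$sex, "male")
  expect_identical(as.integer(holo$individualCount), 1L)
  expect_identical(as.numeric(holo$decimalLatitude), -19.8299)

  s <- summarize_occurrences(occ)
  expect_identical(s$n_records, 9L)
  expect_identical(s$total_individuals, 9L)
})

test_that("the topotypic series sums to the examined specimens", {
  occ <- example_occurrences("viettei")
  expect_identical(nrow(occ), 14L)
  counts <- as.integer(occ$individualCount)
  expect_identical(counts[1:6], c(5L, 13L, 1L, 1L, 1L, 2L))
  expect_identical(sum(counts), 31L)
  s <- summarize_occurrences(occ)
  expect_identical(s$total_individuals, 31L)
  expect_identical(unname(s$individuals_by_species[["Scarabaeus viettei"]]), 31L)
})

test_that("empty input and malformed records are handled", {
  empty <- parse_occurrences("")
  expect_identical(nrow(empty), 0L)
  s <- summarize_occurrences(empty)
  expect_identical(s$n_records, 0L)
  expect_identical(s$total_individuals, 0L)

  expect_error(parse_occurrences("individualCount: 1.5\n"),
               class = "phenoscribe_dwc_count")
  expect_error(parse_occurrences("individualCount: 0\n"),
               class = "phenoscribe_dwc_count")
  expect_error(parse_occurrences("decimalLatitude: -99.2\n"),
               class = "phenoscribe_dwc_coordinate")
  expect_error(parse_occurrences("decimalLongitude: 191\n"),
               class = "phenoscribe_dwc_coordinate")
  expect_error(
    parse_occurrences("occurrenceID: A\n\noccurrenceID: A\n"),
    class = "phenoscribe_dwc_parse")
})

test_that("unknown fields are preserved and verbatim values never rewritten", {
  occ <- parse_occurrences(c("typeStatus: Other material",
                             "individualCount: 2",
                             "fieldNotes: under zebu dung"))
  expect_identical(occ$fieldNotes, "under zebu dung")
  # Madagascar sanity bounds on the bundled records
  for (sp in c("sakalava", "viettei")) {
    occ <- example_occurrences(sp)
    expect_true(all(as.numeric(occ$decimalLatitude) < 0))
    expect_true(all(as.numeric(occ$decimalLongitude) > 0))
    expect_true(all(as.integer(occ$individualCount) >= 1L))
  }
})

test_that("CSV export round-trips losslessly with full printed precision", {
  for (sp in c("sakalava", "viettei")) {
    occ <- example_occurrences(sp)
    csv <- export_dwc_csv(occ)
    expect_identical(strsplit(csv, "\n")[[1]][1],
                     paste0("\"", paste(names(occ), collapse = "\",\""), "\""))
    back <- read_dwc_csv(csv)
    expect_identical(as.data.frame(back), as.data.frame(occ))
  }
  csv <- export_dwc_csv(example_occurrences("sakalava"))
  expect_match(csv, "-19.8299", fixed = TRUE)
  expect_false(grepl("-19.83,", csv, fixed = TRUE))
  one <- export_dwc_csv(parse_occurrences("typeStatus: Holotype\nindividualCount: 1"))
  expect_length(strsplit(one, "\n")[[1]], 2L)
})

test_that("individual totals dominate record counts on any subset", {
  occ <- example_occurrences("viettei")
  set.seed(11)
  for (i in 1:20) {
    idx <- sample(nrow(occ), sample(0:nrow(occ), 1))
    sub <- occ[idx, , drop = FALSE]
    expect_gte(sum(as.integer(sub$individualCount)), nrow(sub))
  }
})

test_that("the label date dialects normalize to ISO intervals", {
  expect_identical(normalize_event_date("12-2006"), "2006-12-01/2006-12-31")
  expect_identical(normalize_event_date("04-2004"), "2004-04-01/2004-04-30")
  expect_identical(normalize_event_date("02-2008"), "2008-02-01/2008-02-29")
  expect_identical(normalize_event_date("23-11-2006"), "2006-11-23")
  expect_identical(normalize_event_date("03/07-03-2022"), "2022-03-03/2022-03-07")
  expect_identical(normalize_event_date("Peyrieras-III"), NA_character_)
  expect_identical(normalize_event_date("13-2006"), NA_character_)
  expect_identical(normalize_event_date(c("12-2006", NA)),
                   c("2006-12-01/2006-12-31", NA))
  # the verbatim column is untouched by normalization
  occ <- example_occurrences("viettei")
  iso <- normalize_event_date(occ$eventDate)
  expect_identical(occ$eventDate[4], "Peyrieras-III")
  expect_true(is.na(iso[4]))
  expect_identical(iso[7], "2006-11-23")
})
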