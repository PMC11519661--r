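# Convenience loaders for the bundled Malagasy Scarabaeus fixtures.

fixture_file <- function(species, suffix) {
  species <- match.arg(species, c("sakalava", "viettei"))
  ps_example(sprintf("scarabaeus_%s_%s", species, suffix))
}

#' Load a bundled male description
#'
#' Parses the transcribed phs source of one of the two bundled *Scarabaeus*
#' male descriptions.
#'
#' @param species `"sakalava"` or `"viettei"`.
#' @param registry A [term_registry()]; defaults to the seeded vocabulary.
#' @return A [semantic_description()].
#' @export
example_description <- function(species = c("sakalava", "viettei"),
                                registry = seed_registry()) {
  read_phs(fixture_file(match.arg(species), "male.phs"), registry)
}

#' Reference clause transcription of a bundled description
#'
#' The published clause text of the corresponding male description,
#' transcribed one clause per line with fully qualified subject paths. This
#' file is maintained independently of the phs source and serves as the
#' textual oracle for rendering and diff tests.
#'
#' @inheritParams example_description
#' @return Character vector of clauses (each ending in `";"`).
#' @export
reference_clauses <- function(species = c("sakalava", "viettei")) {
  lines <- readLines(fixture_file(match.arg(species), "clauses.txt"),
                     encoding = "UTF-8", warn = FALSE)
  lines[nzchar(trimws2(lines))]
}

#' Load the bundled identification key
#'
#' The dichotomous key to adult Malagasy *Scarabaeus* (three couplets, four
#' terminal species).
#'
#' @return A [taxon_key()].
#' @export
example_key <- function() read_key(ps_example("malagasy_scarabaeus_key.yml"))

#' Load bundled occurrence records
#'
#' The Materials records of one of the two bundled species, transcribed to
#' `field: value` record blocks.
#'
#' @inheritParams example_description
#' @return A `dwc_occurrences` data frame.
#' @export
example_occurrences <- function(species = c("sakalava", "viettei")) {
  parse_occurrences(fixture_file(match.arg(species), "materials.txt"))
}
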