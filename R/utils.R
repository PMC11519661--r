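#' @keywords internal
"_PACKAGE"

# classed conditions so callers can distinguish failure modes
ps_stop <- function(subclass, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(subclass, "phenoscribe_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_iri_text <- function(x) {
  grepl("^(https?://|urn:)[^[:space:]]+$", x)
}

trimws2 <- function(x) gsub("^[[:space:]]+|[[:space:]]+$", "", x)

#' Path to a bundled example file
#'
#' Convenience accessor for the plain-text fixtures shipped with the package:
#' the seeded ontology vocabulary, the two transcribed male descriptions
#' (`.phs`), their reference clause transcriptions, the identification key to
#' adult Malagasy *Scarabaeus*, and the Darwin Core materials records.
#'
#' @param file File name under `inst/extdata`; with no argument, lists the
#'   available files.
#' @return A file path, or a character vector of file names.
#' @export
#' @examples
#' ps_example()
#' ps_example("malagasy_scarabaeus_key.yml")
ps_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "phenoscribe")))
  }
  path <- system.file("extdata", file, package = "phenoscribe", mustWork = FALSE)
  if (!nzchar(path)) {
    ps_stop("phenoscribe_missing_file", "no bundled file named '%s'", file)
  }
  path
}
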