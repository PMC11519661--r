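# Darwin Core occurrence records transcribed from taxon-treatment Materials
# blocks: per-record "field: value" lines, blank-line separated. Values are
# kept verbatim (coordinate precision as printed); numeric views are derived
# on demand.

DWC_CORE_FIELDS <- c(
  "typeStatus", "catalogNumber", "recordedBy", "individualCount", "sex",
  "lifeStage", "occurrenceID", "taxonID", "scientificName", "genus",
  "specificEpithet", "scientificNameAuthorship", "country", "stateProvince",
  "locality", "verbatimLocality", "verbatimElevation", "verbatimCoordinates",
  "decimalLatitude", "decimalLongitude", "georeferenceProtocol",
  "georeferenceRemarks", "identifiedBy", "dateIdentified", "eventID",
  "samplingProtocol", "eventDate", "habitat", "institutionID",
  "institutionCode", "basisOfRecord"
)

#' Parse Darwin Core occurrence records
#'
#' Reads a structured text of `field: value` lines grouped per record
#' (records separated by blank lines), as transcribed from the Materials
#' blocks of a taxon treatment. Known Darwin Core term names are arranged
#' first in canonical order; unknown fields are preserved as extra columns.
#' Values are stored verbatim; coordinates and counts are validated on parse.
#'
#' @param source Path to a records file, or the text itself (character vector
#'   of lines or a single string containing newlines).
#' @return A data frame of class `dwc_occurrences`, one row per record, all
#'   columns character (verbatim as printed).
#' @export
parse_occurrences <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, encoding = "UTF-8", warn = FALSE)
  } else {
    lines <- strsplit(paste(source, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  }
  lines <- sub("[[:space:]]+$", "", lines)
  records <- list()
  current <- character()
  flush <- function() {
    if (length(current)) records[[length(records) + 1L]] <<- current
    current <<- character()
  }
  for (ln in lines) {
    if (!nzchar(trimws2(ln))) { flush(); next }
    m <- regmatches(ln, regexec("^([A-Za-z]+):[[:space:]]*(.*)$", ln))[[1]]
    if (length(m) == 0) {
      ps_stop("phenoscribe_dwc_parse", "malformed record line: '%s'", ln)
    }
    current[[m[2]]] <- m[3]
  }
  flush()
  if (!length(records)) {
    out <- as.data.frame(matrix(character(), nrow = 0,
                                ncol = length(DWC_CORE_FIELDS),
                                dimnames = list(NULL, DWC_CORE_FIELDS)),
                         stringsAsFactors = FALSE)
    class(out) <- c("dwc_occurrences", "data.frame")
    return(out)
  }
  fields <- unique(c(intersect(DWC_CORE_FIELDS, unlist(lapply(records, names))),
                     setdiff(unlist(lapply(records, names)), DWC_CORE_FIELDS)))
  out <- as.data.frame(
    lapply(fields, function(f) {
      vapply(records, function(r) if (f %in% names(r)) r[[f]] else NA_character_,
             character(1))
    }), stringsAsFactors = FALSE, optional = TRUE)
  names(out) <- fields
  validate_occurrences(out)
  class(out) <- c("dwc_occurrences", "data.frame")
  out
}

validate_occurrences <- function(df) {
  if ("individualCount" %in% names(df)) {
    vals <- df$individualCount[!is.na(df$individualCount)]
    bad <- vals[!grepl("^[0-9]+$", vals) | suppressWarnings(as.integer(vals)) < 1]
    if (length(bad)) {
      ps_stop("phenoscribe_dwc_count",
              "individualCount must be a positive integer, got: %s",
              paste(unique(bad), collapse = ", "))
    }
  }
  check_coord <- function(col, lo, hi, what) {
    if (!col %in% names(df)) return(invisible())
    vals <- df[[col]][!is.na(df[[col]])]
    num <- suppressWarnings(as.numeric(vals))
    bad <- vals[is.na(num) | num < lo | num > hi]
    if (length(bad)) {
      ps_stop("phenoscribe_dwc_coordinate",
              "invalid %s value(s): %s", what, paste(unique(bad), collapse = ", "))
    }
  }
  check_coord("decimalLatitude", -90, 90, "decimalLatitude")
  check_coord("decimalLongitude", -180, 180, "decimalLongitude")
  if ("occurrenceID" %in% names(df)) {
    ids <- df$occurrenceID[!is.na(df$occurrenceID)]
    if (anyDuplicated(ids)) {
      ps_stop("phenoscribe_dwc_parse", "duplicate occurrenceID within dataset")
    }
  }
  invisible(df)
}

#' Summarize occurrence records
#'
#' @param records A `dwc_occurrences` data frame.
#' @return List with `n_records`, `records_by_type` (table over `typeStatus`),
#'   `total_individuals` (sum of `individualCount`) and `individuals_by_species`.
#' @export
summarize_occurrences <- function(records) {
  counts <- if ("individualCount" %in% names(records)) {
    as.integer(records$individualCount)
  } else {
    rep(1L, nrow(records))
  }
  counts[is.na(counts)] <- 1L
  by_species <- if ("scientificName" %in% names(records) && nrow(records)) {
    tapply(counts, records$scientificName, sum)
  } else {
    integer()
  }
  list(
    n_records = nrow(records),
    records_by_type = if ("typeStatus" %in% names(records)) {
      table(records$typeStatus)
    } else {
      table(character())
    },
    total_individuals = sum(counts),
    individuals_by_species = by_species
  )
}

#' Export occurrence records as Darwin Core CSV
#'
#' One row per record, header of canonical Darwin Core term names, values
#' verbatim (full printed coordinate precision). The output round-trips
#' through [read_dwc_csv()].
#'
#' @param records A `dwc_occurrences` data frame.
#' @param path Optional output path; when `NULL` the CSV text is returned.
#' @return CSV text (invisibly when written to `path`).
#' @export
export_dwc_csv <- function(records, path = NULL) {
  con <- textConnection("out", "w", local = TRUE)
  utils::write.csv(as.data.frame(records), con, row.names = FALSE, na = "")
  close(con)
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

#' Read occurrence records from Darwin Core CSV
#'
#' @param source CSV text or a file path.
#' @return A `dwc_occurrences` data frame (all columns character).
#' @export
read_dwc_csv <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    df <- utils::read.csv(source, colClasses = "character", check.names = FALSE)
  } else {
    df <- utils::read.csv(text = paste(source, collapse = "\n"),
                          colClasses = "character", check.names = FALSE)
  }
  df[df == ""] <- NA_character_
  validate_occurrences(df)
  class(df) <- c("dwc_occurrences", "data.frame")
  df
}

#' Normalize a verbatim event date
#'
#' Recognizes the closed dialect table used on the printed labels:
#' `MM-YYYY` (expanded to the month interval), `DD-MM-YYYY` (a single day)
#' and `DD/DD-MM-YYYY` (a day range within one month). Anything else returns
#' `NA` and the verbatim value is kept by the caller.
#'
#' @param verbatim Character vector of verbatim date strings.
#' @return Character vector of ISO-8601 dates or `start/end` intervals, `NA`
#'   where no dialect matches.
#' @export
normalize_event_date <- function(verbatim) {
  vapply(verbatim, function(v) {
    if (is.na(v)) return(NA_character_)
    v <- trimws2(v)
    m <- regmatches(v, regexec("^([0-9]{2})-([0-9]{4})$", v))[[1]]
    if (length(m)) {
      mo <- as.integer(m[2]); yr <- as.integer(m[3])
      if (mo >= 1 && mo <= 12) {
        last <- c(31, if (yr %% 4 == 0 && (yr %% 100 != 0 || yr %% 400 == 0)) 29 else 28,
                  31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[mo]
        return(sprintf("%04d-%02d-01/%04d-%02d-%02d", yr, mo, yr, mo, last))
      }
      return(NA_character_)
    }
    m <- regmatches(v, regexec("^([0-9]{2})-([0-9]{2})-([0-9]{4})$", v))[[1]]
    if (length(m)) {
      dd <- as.integer(m[2]); mo <- as.integer(m[3]); yr <- as.integer(m[4])
      if (mo >= 1 && mo <= 12 && dd >= 1 && dd <= 31) {
        return(sprintf("%04d-%02d-%02d", yr, mo, dd))
      }
      return(NA_character_)
    }
    m <- regmatches(v, regexec("^([0-9]{2})/([0-9]{2})-([0-9]{2})-([0-9]{4})$", v))[[1]]
    if (length(m)) {
      d1 <- as.integer(m[2]); d2 <- as.integer(m[3])
      mo <- as.integer(m[4]); yr <- as.integer(m[5])
      lo <- min(d1, d2); hi <- max(d1, d2)
      if (mo >= 1 && mo <= 12 && lo >= 1 && hi <= 31) {
        return(sprintf("%04d-%02d-%02d/%04d-%02d-%02d", yr, mo, lo, yr, mo, hi))
      }
      return(NA_character_)
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}
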