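# Statement model for semantic descriptions. Subjects are token vectors
# (root-first); relational objects and comparative references are kept exactly
# as authored, since the rendered reference text shows only the authored
# steps ("length of pronotum", "elytral stria 7 of male organism").

MAGNITUDE_TOKENS <- c("width", "length", "amount")
COMPARATOR_TOKENS <- c("larger_than", "similar_in_magnitude_relative_to")
METADATA_KEYS <- c(catalog_number = "Catalog Number",
                   has_role_in_modeling = "has role in modeling",
                   denotes = "denotes",
                   taxon_id = "Taxon ID",
                   parent_name_usage_id = "Parent Name Usage ID")

new_statement <- function(kind, fields) {
  structure(fields, class = c(paste0("phs_", kind), "phs_statement"))
}

#' Statement constructors
#'
#' Build the five statement variants of a semantic description
#' programmatically. Entity paths are character vectors of prefixed tokens,
#' root-first (e.g. `c("aism-male_organism", "aism-pronotum")`).
#'
#' @param subject Entity path of the bearer (token vector).
#' @param quality Quality token (e.g. `"pato-convex"`).
#' @param relation Relation token flagged as a relation in the registry.
#' @param object Entity path of the relational object, as authored.
#' @param attached_quality Optional quality token attached to the object.
#' @param attribute,ref_attribute Magnitude tokens: one of `width`, `length`,
#'   `amount`.
#' @param comparator One of `larger_than`, `similar_in_magnitude_relative_to`.
#' @param reference Entity path of the comparison reference, as authored.
#' @param value Positive finite measurement value.
#' @param value_text Verbatim decimal text (preserves `23.0` vs `23`).
#' @param unit Unit token (e.g. `"uo-millimeter"`).
#' @param key Metadata key, one of `catalog_number`, `has_role_in_modeling`,
#'   `denotes`, `taxon_id`, `parent_name_usage_id`.
#' @return A `phs_statement` object.
#' @name statements
NULL

#' @rdname statements
#' @export
quality_statement <- function(subject, quality) {
  new_statement("quality", list(subject = subject, quality = quality))
}

#' @rdname statements
#' @export
relational_statement <- function(subject, relation, object,
                                 attached_quality = NULL) {
  new_statement("relational", list(subject = subject, relation = relation,
                                   object = object,
                                   attached_quality = attached_quality))
}

#' @rdname statements
#' @export
comparative_statement <- function(subject, attribute, comparator,
                                  ref_attribute, reference) {
  if (!comparator %in% COMPARATOR_TOKENS) {
    ps_stop("phenoscribe_bad_comparator",
            "unknown comparator '%s' (allowed: %s)", comparator,
            paste(COMPARATOR_TOKENS, collapse = ", "))
  }
  if (!all(c(attribute, ref_attribute) %in% MAGNITUDE_TOKENS)) {
    ps_stop("phenoscribe_bad_comparator",
            "magnitude attribute must be one of %s",
            paste(MAGNITUDE_TOKENS, collapse = ", "))
  }
  new_statement("comparative", list(subject = subject, attribute = attribute,
                                    comparator = comparator,
                                    ref_attribute = ref_attribute,
                                    reference = reference))
}

#' @rdname statements
#' @export
measurement_statement <- function(subject, attribute, value,
                                  unit = "uo-millimeter",
                                  value_text = NULL) {
  value <- as.numeric(value)
  if (!is.finite(value) || value <= 0) {
    ps_stop("phenoscribe_bad_measurement",
            "measurement value must be finite and > 0")
  }
  new_statement("measurement", list(subject = subject, attribute = attribute,
                                    value = value,
                                    value_text = value_text %||% format(value),
                                    unit = unit))
}

#' @rdname statements
#' @export
metadata_statement <- function(key, value) {
  if (!key %in% names(METADATA_KEYS)) {
    ps_stop("phenoscribe_bad_metadata",
            "unknown metadata key '%s' (allowed: %s)", key,
            paste(names(METADATA_KEYS), collapse = ", "))
  }
  new_statement("metadata", list(key = key, value = value))
}

statement_kind <- function(stmt) sub("^phs_", "", class(stmt)[1])

# stable serialization used for equality in round-trip / diff tests
statement_signature <- function(stmt) {
  switch(statement_kind(stmt),
    quality = paste0("Q|", paste(stmt$subject, collapse = ">"), "|", stmt$quality),
    relational = paste0("R|", paste(stmt$subject, collapse = ">"), "|",
                        stmt$relation, "|", paste(stmt$object, collapse = ">"),
                        "|", stmt$attached_quality %||% ""),
    comparative = paste0("C|", paste(stmt$subject, collapse = ">"), "|",
                         stmt$attribute, "|", stmt$comparator, "|",
                         stmt$ref_attribute, "|",
                         paste(stmt$reference, collapse = ">")),
    measurement = paste0("M|", paste(stmt$subject, collapse = ">"), "|",
                         stmt$attribute, "|", stmt$value_text, "|", stmt$unit),
    metadata = paste0("D|", stmt$key, "|", stmt$value)
  )
}

#' Construct a semantic description
#'
#' An ordered collection of phenotype statements about one organism, plus
#' opaque free-text annotations (sexual dimorphism, variation, ...). The
#' authored statement order is preserved exactly; no operation in the package
#' reorders statements.
#'
#' @param taxon_label Taxon name the description documents.
#' @param statements List of `phs_statement` objects.
#' @param annotations Named character vector of free-text annotations.
#' @return An object of class `semantic_description`.
#' @export
semantic_description <- function(taxon_label = "", statements = list(),
                                 annotations = character()) {
  structure(list(taxon_label = taxon_label, statements = statements,
                 annotations = annotations),
            class = "semantic_description")
}

#' @export
print.semantic_description <- function(x, ...) {
  kinds <- vapply(x$statements, statement_kind, character(1))
  cat(sprintf("<semantic_description> %s: %d statements (%s)\n",
              if (nzchar(x$taxon_label)) x$taxon_label else "(unnamed)",
              length(x$statements),
              paste(names(table(kinds)), table(kinds), sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
length.semantic_description <- function(x) length(x$statements)

#' Canonical key of an entity path
#'
#' Deterministic, order-preserving string key: registry labels joined with
#' `" / "`. Two paths are equal iff their keys are equal. For a path holding a
#' grouping step, one key per grouped leaf is returned.
#'
#' @param path Token vector, or an `entity_path` as returned by
#'   [parse_entity_path()].
#' @param registry A [term_registry()].
#' @return Character vector of canonical keys.
#' @export
canonical_path <- function(path, registry) {
  steps <- if (inherits(path, "entity_path")) path$steps else as.list(path)
  expanded <- expand_grouping(steps)
  vapply(expanded, function(tokens) {
    labs <- vapply(tokens, function(tok) resolve_term(registry, tok)$label,
                   character(1))
    paste(labs, collapse = " / ")
  }, character(1))
}

# expand grouping steps (steps of length > 1) into one flat token vector per
# leaf combination, preserving authored member order
expand_grouping <- function(steps) {
  out <- list(character())
  for (step in steps) {
    out <- unlist(lapply(out, function(head) {
      lapply(step, function(member) c(head, member))
    }), recursive = FALSE)
  }
  out
}

#' Extract measurements from a description
#'
#' @param desc A [semantic_description()].
#' @param registry A [term_registry()].
#' @return Data frame with one row per measurement statement, in statement
#'   order: `path` (canonical subject key), `attribute`, `value`, `unit`
#'   (unit label).
#' @export
extract_measurements <- function(desc, registry) {
  rows <- Filter(function(s) statement_kind(s) == "measurement", desc$statements)
  data.frame(
    path = vapply(rows, function(s) canonical_path(s$subject, registry), character(1)),
    attribute = vapply(rows, function(s) s$attribute, character(1)),
    value = vapply(rows, function(s) s$value, numeric(1)),
    unit = vapply(rows, function(s) resolve_term(registry, s$unit)$label, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Validate a description against a registry
#'
#' Unlike [parse_description()], which throws on the first problem, this
#' returns all issues found: unresolvable terms, qualities that are relation
#' terms (or vice versa), comparators outside the closed set, duplicated
#' metadata keys, and syntactically invalid IRI metadata values.
#'
#' @inheritParams extract_measurements
#' @return Character vector of issues; empty when the description is valid.
#' @export
validate_description <- function(desc, registry) {
  issues <- character()
  check_token <- function(tok, what, i) {
    tryCatch({
      resolve_term(registry, tok)
      NULL
    }, phenoscribe_error = function(e) {
      sprintf("statement %d: unresolved %s token '%s' (%s)", i, what, tok,
              conditionMessage(e))
    })
  }
  seen_meta <- character()
  for (i in seq_along(desc$statements)) {
    s <- desc$statements[[i]]
    kind <- statement_kind(s)
    if (kind %in% c("quality", "relational", "comparative", "measurement")) {
      for (tok in s$subject) issues <- c(issues, check_token(tok, "subject", i))
    }
    if (kind == "quality") {
      issues <- c(issues, check_token(s$quality, "quality", i))
      t <- try(resolve_term(registry, s$quality), silent = TRUE)
      if (inherits(t, "onto_term") && t$relation) {
        issues <- c(issues, sprintf(
          "statement %d: quality '%s' is a relation term", i, s$quality))
      }
    } else if (kind == "relational") {
      issues <- c(issues, check_token(s$relation, "relation", i))
      t <- try(resolve_term(registry, s$relation), silent = TRUE)
      if (inherits(t, "onto_term") && !t$relation) {
        issues <- c(issues, sprintf(
          "statement %d: '%s' is not flagged as a relation", i, s$relation))
      }
      for (tok in s$object) issues <- c(issues, check_token(tok, "object", i))
      if (!is.null(s$attached_quality)) {
        issues <- c(issues, check_token(s$attached_quality, "quality", i))
      }
    } else if (kind == "comparative") {
      if (!s$comparator %in% COMPARATOR_TOKENS) {
        issues <- c(issues, sprintf("statement %d: unknown comparator '%s'",
                                    i, s$comparator))
      }
      for (tok in s$reference) issues <- c(issues, check_token(tok, "reference", i))
    } else if (kind == "measurement") {
      issues <- c(issues, check_token(s$unit, "unit", i))
      if (!is.finite(s$value) || s$value <= 0) {
        issues <- c(issues, sprintf("statement %d: non-positive value", i))
      }
    } else if (kind == "metadata") {
      if (s$key %in% seen_meta) {
        issues <- c(issues, sprintf("statement %d: duplicate metadata key '%s'",
                                    i, s$key))
      }
      seen_meta <- c(seen_meta, s$key)
      if (s$key %in% c("catalog_number", "taxon_id", "parent_name_usage_id") &&
          !is_iri_text(s$value)) {
        issues <- c(issues, sprintf(
          "statement %d: metadata '%s' value is not a syntactically valid IRI: '%s'",
          i, s$key, s$value))
      }
    }
  }
  issues[nzchar(issues)]
}
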