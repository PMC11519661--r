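# Deterministic clause-per-statement rendering. One clause per statement,
# flat (fully qualified) subject paths, registry labels throughout; rendering
# is a pure function of (description, registry, format).

comparator_words <- c(larger_than = "larger than",
                      similar_in_magnitude_relative_to = "similar in magnitude relative to")

path_text <- function(tokens, registry) {
  labs <- vapply(tokens, function(tok) resolve_term(registry, tok)$label,
                 character(1))
  paste(labs, collapse = ", ")
}

of_text <- function(tokens, registry) {
  labs <- vapply(tokens, function(tok) resolve_term(registry, tok)$label,
                 character(1))
  paste(rev(labs), collapse = " of ")
}

#' Render one statement as clause text
#'
#' Path terms are joined with `", "`, the quality follows `": "`, relations
#' are spelled with spaces, reference paths are reversed and `" of "`-joined,
#' measurements render as `"length = 23.0, unit: millimeter"`. Every clause is
#' terminated by `";"`.
#'
#' @param stmt A `phs_statement`.
#' @param registry A [term_registry()].
#' @return Clause text (character scalar).
#' @export
render_statement <- function(stmt, registry) {
  kind <- statement_kind(stmt)
  body <- switch(kind,
    quality = sprintf("%s: %s",
                      path_text(stmt$subject, registry),
                      resolve_term(registry, stmt$quality)$label),
    relational = {
      base <- sprintf("%s %s %s",
                      path_text(stmt$subject, registry),
                      resolve_term(registry, stmt$relation)$label,
                      of_text(stmt$object, registry))
      if (!is.null(stmt$attached_quality)) {
        base <- sprintf("%s: %s", base,
                        resolve_term(registry, stmt$attached_quality)$label)
      }
      base
    },
    comparative = sprintf("%s: %s %s %s of %s",
                          path_text(stmt$subject, registry),
                          stmt$attribute,
                          comparator_words[[stmt$comparator]],
                          stmt$ref_attribute,
                          of_text(stmt$reference, registry)),
    measurement = sprintf("%s, %s = %s, unit: %s",
                          path_text(stmt$subject, registry),
                          stmt$attribute, stmt$value_text,
                          resolve_term(registry, stmt$unit)$label),
    metadata = sprintf("%s: %s", METADATA_KEYS[[stmt$key]], stmt$value)
  )
  paste0(body, ";")
}

#' Render a description to markdown or HTML
#'
#' Markdown output carries the taxon label and free-text annotations as
#' `@`-directive lines followed by one clause per line, and is itself valid
#' phs input: `parse_description(render_description(d)$text)` recovers `d`
#' statement-for-statement (the parse/render fixpoint). HTML output wraps the
#' clauses in a list for display and does not round-trip.
#'
#' @param desc A [semantic_description()].
#' @param registry A [term_registry()].
#' @param format `"markdown"` or `"html"`.
#' @return An object of class `rendered_description` with fields `clauses`
#'   (ordered character vector, one per statement), `format` and `text`.
#' @export
render_description <- function(desc, registry,
                               format = c("markdown", "html")) {
  format <- tryCatch(match.arg(format), error = function(e) {
    ps_stop("phenoscribe_unsupported_format",
            "unsupported render format '%s'", format[1])
  })
  clauses <- vapply(desc$statements, render_statement, character(1),
                    registry = registry)
  if (format == "markdown") {
    head <- character()
    if (nzchar(desc$taxon_label)) {
      head <- c(head, paste("@taxon", desc$taxon_label))
    }
    for (nm in names(desc$annotations)) {
      head <- c(head, paste("@note", nm, desc$annotations[[nm]]))
    }
    text <- paste(c(head, if (length(head)) "", clauses), collapse = "\n")
  } else {
    esc <- function(x) {
      x <- gsub("&", "&amp;", x, fixed = TRUE)
      x <- gsub("<", "&lt;", x, fixed = TRUE)
      gsub(">", "&gt;", x, fixed = TRUE)
    }
    body <- c(
      if (nzchar(desc$taxon_label)) sprintf("<h1>%s</h1>", esc(desc$taxon_label)),
      "<ul>",
      sprintf("  <li>%s</li>", esc(clauses)),
      "</ul>",
      unlist(lapply(names(desc$annotations), function(nm) {
        c(sprintf("<h2>%s</h2>", esc(gsub("_", " ", nm))),
          sprintf("<p>%s</p>", esc(desc$annotations[[nm]])))
      }))
    )
    text <- paste(body, collapse = "\n")
  }
  structure(list(clauses = clauses, format = format, text = text),
            class = "rendered_description")
}

#' @export
print.rendered_description <- function(x, ...) {
  cat(x$text, "\n", sep = "")
  invisible(x)
}
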