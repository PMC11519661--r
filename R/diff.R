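# Statement-level diff between two descriptions, the machinery behind a
# taxonomic diagnosis. Statements are matched by canonical subject path +
# statement kind (+ attribute / relation); qualities of a shared subject are
# compared as multisets with leftovers paired in authored order.

diff_key <- function(stmt, registry) {
  kind <- statement_kind(stmt)
  switch(kind,
    quality = paste0("quality|", canonical_path(stmt$subject, registry)),
    relational = paste0("relational|", canonical_path(stmt$subject, registry),
                        "|", stmt$relation),
    comparative = paste0("comparative|", canonical_path(stmt$subject, registry),
                         "|", stmt$attribute),
    measurement = paste0("measurement|", canonical_path(stmt$subject, registry),
                         "|", stmt$attribute),
    metadata = paste0("metadata|", stmt$key)
  )
}

diff_value <- function(stmt, registry) {
  switch(statement_kind(stmt),
    quality = resolve_term(registry, stmt$quality)$label,
    relational = {
      v <- of_text(stmt$object, registry)
      if (!is.null(stmt$attached_quality)) {
        v <- paste0(v, ": ", resolve_term(registry, stmt$attached_quality)$label)
      }
      v
    },
    comparative = sprintf("%s %s %s of %s", stmt$attribute,
                          comparator_words[[stmt$comparator]],
                          stmt$ref_attribute, of_text(stmt$reference, registry)),
    measurement = stmt$value_text,
    metadata = stmt$value
  )
}

key_path <- function(key) strsplit(key, "|", fixed = TRUE)[[1]][2]
key_kind <- function(key) strsplit(key, "|", fixed = TRUE)[[1]][1]

#' Diff two semantic descriptions
#'
#' Computes the statement-level differences that make up a diagnosis.
#' Statements are matched by canonical subject path and statement kind;
#' qualities are compared term-wise, measurements numerically. A subject path
#' present in only one description (a structural difference, e.g. an extra
#' anatomical level) contributes to `only_in_a` / `only_in_b`; shared subjects
#' with differing values contribute to `changed`; differing measurements go to
#' `measurement_deltas`. `diff_descriptions(x, x)` is empty in every bucket.
#'
#' @param a,b [semantic_description()] objects validating against `registry`.
#' @param registry A [term_registry()]; both descriptions must resolve
#'   against it.
#' @return An object of class `description_diff` with fields `only_in_a`,
#'   `only_in_b` (data frames: `path`, `kind`, `value`), `changed` (data
#'   frame: `path`, `kind`, `value_a`, `value_b`) and `measurement_deltas`
#'   (data frame: `path`, `attribute`, `value_a`, `value_b`).
#' @export
diff_descriptions <- function(a, b, registry) {
  for (d in list(a, b)) {
    issues <- validate_description(d, registry)
    if (length(issues)) {
      ps_stop("phenoscribe_registry_mismatch",
              "description '%s' does not validate against the registry:\n%s",
              d$taxon_label, paste("-", issues, collapse = "\n"))
    }
  }
  index <- function(desc) {
    keys <- vapply(desc$statements, diff_key, character(1), registry = registry)
    vals <- vapply(desc$statements, diff_value, character(1), registry = registry)
    split(vals, factor(keys, levels = unique(keys)))
  }
  ia <- index(a); ib <- index(b)
  all_keys <- union(names(ia), names(ib))

  only_a <- list(); only_b <- list(); changed <- list(); deltas <- list()
  push <- function(store, row) c(store, list(row))

  for (key in all_keys) {
    va <- ia[[key]] %||% character()
    vb <- ib[[key]] %||% character()
    kind <- key_kind(key)
    path <- key_path(key)
    # remove values common to both sides (multiset intersection)
    keep_a <- rep(TRUE, length(va)); keep_b <- rep(TRUE, length(vb))
    for (i in seq_along(va)) {
      j <- which(keep_b & vb == va[i])
      if (length(j)) { keep_a[i] <- FALSE; keep_b[j[1]] <- FALSE }
    }
    ra <- va[keep_a]; rb <- vb[keep_b]
    n_pair <- min(length(ra), length(rb))
    if (n_pair > 0) {
      for (i in seq_len(n_pair)) {
        if (kind == "measurement") {
          deltas <- push(deltas, data.frame(
            path = path, attribute = strsplit(key, "|", fixed = TRUE)[[1]][3],
            value_a = as.numeric(ra[i]), value_b = as.numeric(rb[i]),
            stringsAsFactors = FALSE))
        } else {
          changed <- push(changed, data.frame(
            path = path, kind = kind, value_a = ra[i], value_b = rb[i],
            stringsAsFactors = FALSE))
        }
      }
    }
    if (length(ra) > n_pair) {
      for (v in ra[(n_pair + 1):length(ra)]) {
        only_a <- push(only_a, data.frame(path = path, kind = kind, value = v,
                                          stringsAsFactors = FALSE))
      }
    }
    if (length(rb) > n_pair) {
      for (v in rb[(n_pair + 1):length(rb)]) {
        only_b <- push(only_b, data.frame(path = path, kind = kind, value = v,
                                          stringsAsFactors = FALSE))
      }
    }
  }
  bindrows <- function(rows, template) {
    if (length(rows)) do.call(rbind, rows) else template
  }
  structure(list(
    only_in_a = bindrows(only_a, data.frame(path = character(), kind = character(),
                                            value = character())),
    only_in_b = bindrows(only_b, data.frame(path = character(), kind = character(),
                                            value = character())),
    changed = bindrows(changed, data.frame(path = character(), kind = character(),
                                           value_a = character(),
                                           value_b = character())),
    measurement_deltas = bindrows(deltas, data.frame(path = character(),
                                                     attribute = character(),
                                                     value_a = numeric(),
                                                     value_b = numeric())),
    label_a = a$taxon_label, label_b = b$taxon_label
  ), class = "description_diff")
}

#' @export
print.description_diff <- function(x, ...) {
  cat(sprintf("<description_diff> %s vs %s\n",
              if (nzchar(x$label_a)) x$label_a else "a",
              if (nzchar(x$label_b)) x$label_b else "b"))
  cat(sprintf("  changed: %d | only in a: %d | only in b: %d | measurement deltas: %d\n",
              nrow(x$changed), nrow(x$only_in_a), nrow(x$only_in_b),
              nrow(x$measurement_deltas)))
  invisible(x)
}

#' Render a diff as diagnostic character lines
#'
#' One human-readable line per changed entry, per structural difference and
#' per measurement delta, in a stable order (changed, only-in-a, only-in-b,
#' measurements).
#'
#' @param report A `description_diff`.
#' @return Character vector of diagnostic lines; empty for an empty report.
#' @export
summarize_diagnosis <- function(report) {
  la <- if (nzchar(report$label_a)) report$label_a else "first"
  lb <- if (nzchar(report$label_b)) report$label_b else "second"
  lines <- character()
  ch <- report$changed
  for (i in seq_len(nrow(ch))) {
    lines <- c(lines, sprintf("%s: %s in %s, %s in %s;", ch$path[i],
                              ch$value_a[i], la, ch$value_b[i], lb))
  }
  oa <- report$only_in_a
  for (i in seq_len(nrow(oa))) {
    lines <- c(lines, sprintf("%s: %s, only in %s;", oa$path[i], oa$value[i], la))
  }
  ob <- report$only_in_b
  for (i in seq_len(nrow(ob))) {
    lines <- c(lines, sprintf("%s: %s, only in %s;", ob$path[i], ob$value[i], lb))
  }
  md <- report$measurement_deltas
  for (i in seq_len(nrow(md))) {
    lines <- c(lines, sprintf("%s: %s = %s in %s, %s in %s;", md$path[i],
                              md$attribute[i], format(md$value_a[i]), la,
                              format(md$value_b[i]), lb))
  }
  lines
}
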