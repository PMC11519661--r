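# Parser for the phs dialect.
#
# Source form (authored files):
#   - one statement per ";", comments from "#" to end of line
#   - "@key value" metadata lines precede the phenotype statements
#   - entity paths chain terms with ">" (implicit part-of); a step may be a
#     grouping "(tok, tok, ...)" of sibling terms
#   - "path : pato-quality ;"                        quality
#   - "path .ro-relation path [: pato-quality] ;"    relational
#   - "path : width larger_than length of path ;"    comparative
#   - "path : length = 23.0 uo-millimeter ;"         measurement
#   - "path { ... }" opens a block: nested statement subjects are resolved
#     against the block path; a statement starting with ":" or "." applies to
#     the block subject itself
#
# Label form (the renderer's output, accepted so that parse -> render ->
# parse is a fixpoint): paths are ", "-joined registry labels, relations are
# spelled with spaces, references are reversed and " of "-joined.

TOKEN_RE <- "[A-Za-z][A-Za-z0-9]*-[a-z0-9_]+"

#' Parse a phs description
#'
#' Parses Phenoscript-style DSL text into an ordered [semantic_description()].
#' Both the authored token form and the rendered label form are accepted (see
#' the package vignette for the dialect definition). Grouping steps are
#' expanded into one statement per grouped leaf, matching the published
#' clause-per-leaf style.
#'
#' @param text DSL source: a character scalar or vector of lines.
#' @param registry A [term_registry()]; every term token must resolve.
#' @return A [semantic_description()].
#' @export
parse_description <- function(text, registry) {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  lines <- sub("(^|[[:space:]])#.*$", "\\1", lines)

  taxon_label <- ""
  annotations <- character()
  meta_statements <- list()
  statements <- list()
  seen_meta <- character()
  body_started <- FALSE

  block_stack <- list()
  cur <- ""
  cur_line <- NA_integer_

  flush_statement <- function(txt, line) {
    txt <- trimws2(txt)
    if (!nzchar(txt)) return(invisible())
    prefix <- unlist(block_stack)
    parsed <- tryCatch(
      parse_statement_text(txt, prefix, registry),
      phenoscribe_error = function(e) {
        ps_stop(class(e)[1], "line %d: %s", line, conditionMessage(e))
      })
    for (s in parsed) {
      if (statement_kind(s) == "metadata") {
        if (s$key %in% seen_meta) {
          ps_stop("phenoscribe_duplicate_metadata",
                  "line %d: duplicate metadata key '%s'", line, s$key)
        }
        seen_meta <<- c(seen_meta, s$key)
        meta_statements[[length(meta_statements) + 1L]] <<- s
      } else {
        statements[[length(statements) + 1L]] <<- s
        body_started <<- TRUE
      }
    }
    invisible()
  }

  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws2(cur))) {
      m <- regmatches(line, regexec("^[[:space:]]*@([a-z_]+)[[:space:]]+(.*)$", line))[[1]]
      if (length(m)) {
        key <- m[2]; value <- trimws2(m[3])
        if (key == "taxon") {
          taxon_label <- value
        } else if (key == "note") {
          nm <- regmatches(value, regexec("^([a-z_]+)[[:space:]]+(.*)$", value))[[1]]
          if (length(nm) == 0) {
            ps_stop("phenoscribe_syntax", "line %d: malformed @note line", ln)
          }
          annotations[[nm[2]]] <- trimws2(nm[3])
        } else if (key %in% names(METADATA_KEYS)) {
          if (body_started) {
            ps_stop("phenoscribe_syntax",
                    "line %d: metadata line after phenotype statements", ln)
          }
          if (key %in% seen_meta) {
            ps_stop("phenoscribe_duplicate_metadata",
                    "line %d: duplicate metadata key '%s'", ln, key)
          }
          seen_meta <- c(seen_meta, key)
          meta_statements[[length(meta_statements) + 1L]] <-
            metadata_statement(key, value)
        } else {
          ps_stop("phenoscribe_syntax", "line %d: unknown directive '@%s'", ln, key)
        }
        next
      }
    }
    chars <- strsplit(line, "", fixed = TRUE)[[1]]
    for (ch in chars) {
      if (ch == ";") {
        flush_statement(cur, if (is.na(cur_line)) ln else cur_line)
        cur <- ""; cur_line <- NA_integer_
      } else if (ch == "{") {
        header <- trimws2(cur)
        if (!nzchar(header)) {
          ps_stop("phenoscribe_syntax", "line %d: block without a subject path", ln)
        }
        steps <- parse_source_path(header, registry, allow_group = FALSE)
        block_stack[[length(block_stack) + 1L]] <- unlist(steps)
        cur <- ""; cur_line <- NA_integer_
      } else if (ch == "}") {
        if (nzchar(trimws2(cur))) {
          ps_stop("phenoscribe_syntax",
                  "line %d: statement not terminated by ';' before '}'", ln)
        }
        if (!length(block_stack)) {
          ps_stop("phenoscribe_syntax", "line %d: unmatched '}'", ln)
        }
        block_stack[[length(block_stack)]] <- NULL
        cur <- ""; cur_line <- NA_integer_
      } else {
        if (!nzchar(trimws2(cur)) && nzchar(trimws2(ch))) cur_line <- ln
        cur <- paste0(cur, ch)
      }
    }
    cur <- paste0(cur, " ")
  }
  if (nzchar(trimws2(cur))) {
    ps_stop("phenoscribe_syntax", "unterminated statement at end of input: '%s'",
            trimws2(cur))
  }
  if (length(block_stack)) {
    ps_stop("phenoscribe_syntax", "unclosed block at end of input")
  }
  semantic_description(taxon_label = taxon_label,
                       statements = c(meta_statements, statements),
                       annotations = annotations)
}

#' Read a phs file
#'
#' @param path Path to a UTF-8 `.phs` file.
#' @param registry A [term_registry()].
#' @return A [semantic_description()].
#' @export
read_phs <- function(path, registry) {
  parse_description(readLines(path, encoding = "UTF-8", warn = FALSE), registry)
}

# ---- statement-level parsing -------------------------------------------------

parse_statement_text <- function(txt, prefix, registry) {
  first <- substr(txt, 1, 1)
  if (first %in% c(":", ".") || grepl(sprintf("^%s([[:space:]>(]|$)", TOKEN_RE), txt)) {
    parse_source_statement(txt, prefix, registry)
  } else {
    parse_label_statement(txt, registry)
  }
}

parse_source_statement <- function(txt, prefix, registry) {
  make_subjects <- function(left) {
    left <- trimws2(left)
    if (!nzchar(left)) {
      if (!length(prefix)) {
        ps_stop("phenoscribe_syntax",
                "statement without a subject outside any block: '%s'", txt)
      }
      return(list(prefix))
    }
    steps <- parse_source_path(left, registry)
    lapply(expand_grouping(steps), function(tokens) c(prefix, tokens))
  }

  rel_m <- regexpr(sprintf("(^|[[:space:]])\\.(%s)", TOKEN_RE), txt)
  if (rel_m > 0) {
    match_text <- regmatches(txt, rel_m)
    rel_token <- sub("^[[:space:]]*\\.", "", match_text)
    left <- substr(txt, 1, rel_m - 1)
    rest <- trimws2(substr(txt, rel_m + attr(rel_m, "match.length"), nchar(txt)))
    rel_term <- resolve_term(registry, rel_token)
    if (!rel_term$relation) {
      ps_stop("phenoscribe_not_relation",
              "'%s' is not flagged as a relation in the registry", rel_token)
    }
    q_m <- regexec(sprintf("^(.*?)[[:space:]]*:[[:space:]]*(%s)$", TOKEN_RE), rest)[[1]]
    attached <- NULL
    if (q_m[1] > 0) {
      parts <- regmatches(rest, regexec(
        sprintf("^(.*?)[[:space:]]*:[[:space:]]*(%s)$", TOKEN_RE), rest))[[1]]
      rest <- parts[2]
      attached <- parts[3]
      resolve_term(registry, attached)
    }
    object <- unlist(parse_source_path(rest, registry, allow_group = FALSE))
    return(lapply(make_subjects(left), function(subj) {
      relational_statement(subj, rel_token, object, attached)
    }))
  }

  colon <- regexpr(":", txt, fixed = TRUE)
  if (colon < 0) {
    ps_stop("phenoscribe_syntax", "cannot parse statement: '%s'", txt)
  }
  left <- substr(txt, 1, colon - 1)
  rhs <- trimws2(substr(txt, colon + 1, nchar(txt)))

  meas <- regmatches(rhs, regexec(sprintf(
    "^(%s)[[:space:]]*=[[:space:]]*([0-9]+\\.?[0-9]*)[[:space:]]+(%s)$",
    paste(MAGNITUDE_TOKENS, collapse = "|"), TOKEN_RE), rhs))[[1]]
  if (length(meas)) {
    resolve_term(registry, meas[4])
    return(lapply(make_subjects(left), function(subj) {
      measurement_statement(subj, meas[2], as.numeric(meas[3]),
                            unit = meas[4], value_text = meas[3])
    }))
  }

  comp <- regmatches(rhs, regexec(sprintf(
    "^(%s)[[:space:]]+(%s)[[:space:]]+(%s)[[:space:]]+of[[:space:]]+(.+)$",
    paste(MAGNITUDE_TOKENS, collapse = "|"),
    paste(COMPARATOR_TOKENS, collapse = "|"),
    paste(MAGNITUDE_TOKENS, collapse = "|")), rhs))[[1]]
  if (length(comp)) {
    reference <- unlist(parse_source_path(comp[5], registry, allow_group = FALSE))
    return(lapply(make_subjects(left), function(subj) {
      comparative_statement(subj, comp[2], comp[3], comp[4], reference)
    }))
  }

  if (grepl(sprintf("^%s$", TOKEN_RE), rhs)) {
    q <- resolve_term(registry, rhs)
    if (q$relation) {
      ps_stop("phenoscribe_not_quality",
              "relation term '%s' used as a quality", rhs)
    }
    return(lapply(make_subjects(left), function(subj) {
      quality_statement(subj, rhs)
    }))
  }
  ps_stop("phenoscribe_syntax", "cannot parse statement tail ': %s'", rhs)
}

# split a source path "a > b > (c, d)" into a list of steps; each step is a
# character vector (length > 1 for grouping steps)
parse_source_path <- function(txt, registry, allow_group = TRUE) {
  parts <- strsplit(txt, ">", fixed = TRUE)[[1]]
  # re-join parts split inside a grouping "( ... , ... )": groupings contain
  # "," not ">", so a plain split is safe
  steps <- lapply(trimws2(parts), function(p) {
    if (grepl("^\\(.*\\)$", p)) {
      if (!allow_group) {
        ps_stop("phenoscribe_syntax", "grouping not allowed here: '%s'", p)
      }
      members <- trimws2(strsplit(sub("^\\((.*)\\)$", "\\1", p), ",",
                                  fixed = TRUE)[[1]])
      if (!length(members)) {
        ps_stop("phenoscribe_syntax", "empty grouping in path '%s'", txt)
      }
      for (tok in members) resolve_term(registry, tok)
      members
    } else {
      if (!grepl(sprintf("^%s$", TOKEN_RE), p)) {
        ps_stop("phenoscribe_syntax", "malformed path step '%s'", p)
      }
      resolve_term(registry, p)
      p
    }
  })
  if (!length(steps)) ps_stop("phenoscribe_syntax", "empty entity path")
  steps
}

#' Parse an entity path expression
#'
#' Parses a single source-form path such as
#' `"aism-antenna_with_9_antennomeres > colao-antennal_club >
#' (aism-flagellomere_5, aism-flagellomere_6, aism-flagellomere_7)"` into an
#' `entity_path` whose steps may include a grouping of sibling terms.
#'
#' @param text Path expression.
#' @param registry A [term_registry()].
#' @return An object of class `entity_path` with a `steps` list; grouping
#'   steps are character vectors of length > 1.
#' @export
parse_entity_path <- function(text, registry) {
  structure(list(steps = parse_source_path(text, registry)),
            class = "entity_path")
}

#' @export
print.entity_path <- function(x, ...) {
  step_txt <- vapply(x$steps, function(s) {
    if (length(s) > 1) paste0("(", paste(s, collapse = ", "), ")") else s
  }, character(1))
  cat("<entity_path>", paste(step_txt, collapse = " > "), "\n")
  invisible(x)
}

# ---- label-form parsing ------------------------------------------------------

parse_label_statement <- function(txt, registry) {
  for (key in names(METADATA_KEYS)) {
    lab <- METADATA_KEYS[[key]]
    m <- regmatches(txt, regexec(
      sprintf("^%s:[[:space:]]*(.+)$", lab), txt))[[1]]
    if (length(m)) return(list(metadata_statement(key, trimws2(m[2]))))
  }

  rels <- relation_terms(registry)
  rel_labels <- vapply(rels, function(t) t$label, character(1))
  rel_tokens <- vapply(rels, render_token, character(1))
  ord <- order(-nchar(rel_labels))
  for (i in ord) {
    pat <- sprintf(" %s ", rel_labels[i])
    pos <- regexpr(pat, txt, fixed = TRUE)
    if (pos > 0) {
      left <- substr(txt, 1, pos - 1)
      rest <- trimws2(substr(txt, pos + attr(pos, "match.length"), nchar(txt)))
      attached <- NULL
      qm <- regmatches(rest, regexec("^(.*?): (.+)$", rest))[[1]]
      if (length(qm)) {
        qt <- label_term(registry, trimws2(qm[3]), required = FALSE)
        if (!is.null(qt) && !qt$relation) {
          rest <- trimws2(qm[2])
          attached <- render_token(qt)
        }
      }
      subject <- labels_to_tokens(registry, strsplit(left, ", ", fixed = TRUE)[[1]])
      object <- rev(segment_of_path(rest, registry))
      return(list(relational_statement(subject, rel_tokens[i], object, attached)))
    }
  }

  em <- regmatches(txt, regexec(sprintf(
    "^(.+), (%s) = ([0-9]+\\.?[0-9]*), unit: (.+)$",
    paste(MAGNITUDE_TOKENS, collapse = "|")), txt))[[1]]
  if (length(em)) {
    subject <- labels_to_tokens(registry, strsplit(em[2], ", ", fixed = TRUE)[[1]])
    unit <- label_term(registry, trimws2(em[5]))
    return(list(measurement_statement(subject, em[3], as.numeric(em[4]),
                                      unit = render_token(unit),
                                      value_text = em[4])))
  }

  colon <- regexpr(": ", txt, fixed = TRUE)
  if (colon < 0) {
    ps_stop("phenoscribe_syntax", "cannot parse rendered clause: '%s'", txt)
  }
  left <- substr(txt, 1, colon - 1)
  rhs <- trimws2(substr(txt, colon + 2, nchar(txt)))
  comp_words <- c(larger_than = "larger than",
                  similar_in_magnitude_relative_to = "similar in magnitude relative to")
  cpat <- sprintf("^(%s) (%s) (%s) of (.+)$",
                  paste(MAGNITUDE_TOKENS, collapse = "|"),
                  paste(comp_words, collapse = "|"),
                  paste(MAGNITUDE_TOKENS, collapse = "|"))
  cm <- regmatches(rhs, regexec(cpat, rhs))[[1]]
  subject <- labels_to_tokens(registry, strsplit(left, ", ", fixed = TRUE)[[1]])
  if (length(cm)) {
    comparator <- names(comp_words)[match(cm[3], comp_words)]
    reference <- rev(segment_of_path(cm[5], registry))
    return(list(comparative_statement(subject, cm[2], comparator, cm[4], reference)))
  }
  q <- label_term(registry, rhs)
  if (q$relation) {
    ps_stop("phenoscribe_not_quality", "relation term '%s' used as a quality", rhs)
  }
  list(quality_statement(subject, render_token(q)))
}

label_term <- function(registry, label, required = TRUE) {
  t <- resolve_label(registry, label)
  if (is.null(t) && required) {
    ps_stop("phenoscribe_unknown_term", "no registered term labelled '%s'", label)
  }
  t
}

labels_to_tokens <- function(registry, labels) {
  vapply(trimws2(labels), function(lab) {
    render_token(label_term(registry, lab))
  }, character(1), USE.NAMES = FALSE)
}

# Segment a rendered reference like
#   "simple setigerous cuticular puncture of proximal region of row of punctures"
# into leaf-first labels, backtracking so that labels containing " of "
# ("row of punctures") are kept whole. Returns leaf-first token vector.
segment_of_path <- function(text, registry) {
  parts <- strsplit(text, " of ", fixed = TRUE)[[1]]
  n <- length(parts)
  recurse <- function(i) {
    if (i > n) return(list())
    for (j in i:n) {
      candidate <- paste(parts[i:j], collapse = " of ")
      t <- resolve_label(registry, candidate)
      if (!is.null(t)) {
        rest <- recurse(j + 1)
        if (!is.null(rest)) return(c(list(render_token(t)), rest))
      }
    }
    NULL
  }
  out <- recurse(1)
  if (is.null(out)) {
    ps_stop("phenoscribe_unknown_term",
            "cannot segment reference path '%s' into registered labels", text)
  }
  unlist(out)
}
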