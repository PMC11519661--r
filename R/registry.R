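# Ontology term registry: prefixed controlled vocabulary with ID minting and
# a symmetric homology store. The registry is an environment so that
# registration mutates in place (one registry is threaded through a whole
# parse/compile/diff session).

new_onto_term <- function(prefix, local_name, label = NULL, numeric_id = NULL,
                          definition = NULL, relation = FALSE) {
  if (!grepl("^[A-Za-z][A-Za-z0-9]*$", prefix)) {
    ps_stop("phenoscribe_bad_term", "invalid prefix token '%s'", prefix)
  }
  if (!grepl("^[a-z0-9_]+$", local_name)) {
    ps_stop("phenoscribe_bad_term", "invalid local name '%s'", local_name)
  }
  if (!is.null(numeric_id)) {
    if (!grepl("^[0-9]{7}$", numeric_id)) {
      ps_stop("phenoscribe_bad_term",
              "numeric id must be exactly 7 decimal digits, got '%s'", numeric_id)
    }
  }
  label <- label %||% gsub("_", " ", local_name)
  if (!nzchar(label)) ps_stop("phenoscribe_bad_term", "term label must be non-empty")
  structure(
    list(prefix = toupper(prefix), local_name = local_name, label = label,
         numeric_id = numeric_id, definition = definition,
         relation = isTRUE(relation)),
    class = "onto_term"
  )
}

#' @export
print.onto_term <- function(x, ...) {
  cat(sprintf("<onto_term> %s (%s%s)\n", render_token(x), x$label,
              if (x$relation) ", relation" else ""))
  invisible(x)
}

term_key <- function(prefix, local_name) paste0(toupper(prefix), ":", local_name)

#' Create an empty term registry
#'
#' A registry holds ontology terms keyed by `(prefix, local_name)`, a prefix
#' table mapping namespace tokens to IRI bases, and a symmetric homology
#' store. All lookups are deterministic.
#'
#' @param prefixes Named character vector of `PREFIX = IRI base` pairs.
#' @return An object of class `term_registry`.
#' @export
term_registry <- function(prefixes = character()) {
  env <- new.env(parent = emptyenv())
  env$terms <- list()
  env$prefix_table <- character()
  env$homologies <- character()
  reg <- structure(list(env = env), class = "term_registry")
  for (p in names(prefixes)) register_prefix(reg, p, prefixes[[p]])
  reg
}

#' @export
print.term_registry <- function(x, ...) {
  cat(sprintf("<term_registry> %d terms, %d prefixes, %d homology records\n",
              length(x$env$terms), length(x$env$prefix_table),
              length(x$env$homologies)))
  invisible(x)
}

#' Register a namespace prefix
#'
#' @param registry A [term_registry()].
#' @param prefix Namespace token (stored uppercased).
#' @param iri_base IRI base the prefix expands to.
#' @return The registry, invisibly.
#' @export
register_prefix <- function(registry, prefix, iri_base) {
  registry$env$prefix_table[[toupper(prefix)]] <- iri_base
  invisible(registry)
}

#' Register an ontology term
#'
#' @inheritParams register_prefix
#' @param local_name Lowercase snake_case token.
#' @param label Human-readable label; defaults to the local name with
#'   underscores replaced by spaces.
#' @param numeric_id Optional zero-padded 7-digit identifier string.
#' @param definition Optional free-text definition.
#' @param relation Whether the term is a relation (part-of, homology,
#'   adjacency, ...), usable as the predicate of a relational statement.
#' @return The registered [onto_term], invisibly.
#' @export
register_term <- function(registry, prefix, local_name, label = NULL,
                          numeric_id = NULL, definition = NULL,
                          relation = FALSE) {
  term <- new_onto_term(prefix, local_name, label, numeric_id, definition, relation)
  if (!term$prefix %in% names(registry$env$prefix_table)) {
    ps_stop("phenoscribe_unknown_prefix",
            "prefix '%s' is not registered in the prefix table", term$prefix)
  }
  key <- term_key(term$prefix, term$local_name)
  if (!is.null(registry$env$terms[[key]])) {
    ps_stop("phenoscribe_term_collision", "term '%s' already registered", key)
  }
  registry$env$terms[[key]] <- term
  invisible(term)
}

#' Resolve a prefixed DSL token to a registered term
#'
#' Tokens have the shape `<prefix>-<local_name>` (e.g. `aism-flagellomere_5`,
#' `ro-in_homology_relationship_with`). Resolution is case-normalizing on the
#' prefix only.
#'
#' @inheritParams register_prefix
#' @param token Prefixed token.
#' @return The unique registered [onto_term].
#' @export
resolve_term <- function(registry, token) {
  m <- regmatches(token, regexec("^([A-Za-z][A-Za-z0-9]*)-([a-z0-9_]+)$", token))[[1]]
  if (length(m) == 0) {
    ps_stop("phenoscribe_malformed_token",
            "malformed term token '%s' (expected <prefix>-<local_name>)", token)
  }
  prefix <- toupper(m[2]); local <- m[3]
  if (!prefix %in% names(registry$env$prefix_table)) {
    ps_stop("phenoscribe_unknown_prefix",
            "unknown prefix '%s' in token '%s'", tolower(prefix), token)
  }
  term <- registry$env$terms[[term_key(prefix, local)]]
  if (is.null(term)) {
    ps_stop("phenoscribe_unknown_term",
            "no term '%s' registered under prefix '%s'", local, prefix)
  }
  term
}

#' Render a term back to its DSL token
#'
#' Inverse of [resolve_term()]: `resolve_term(r, render_token(t))` returns `t`
#' for every registered term.
#'
#' @param term An [onto_term].
#' @return The `<prefix>-<local_name>` token (lowercase prefix).
#' @export
render_token <- function(term) paste0(tolower(term$prefix), "-", term$local_name)

#' Resolve a human-readable label to a term token
#'
#' Used when parsing rendered (label-form) clauses back into statements.
#' Labels are required to be unique across the registry.
#'
#' @inheritParams register_prefix
#' @param label Term label as rendered (e.g. "antenna with 9 antennomeres").
#' @return The matching token, or `NULL` if no term carries the label.
#' @export
resolve_label <- function(registry, label) {
  idx <- label_index(registry)
  key <- idx[[label]]
  if (is.null(key) || is.na(key)) return(NULL)
  registry$env$terms[[key]]
}

label_index <- function(registry) {
  terms <- registry$env$terms
  labs <- vapply(terms, function(t) t$label, character(1))
  if (anyDuplicated(labs)) {
    dup <- unique(labs[duplicated(labs)])
    ps_stop("phenoscribe_ambiguous_label",
            "registry labels are not unique: %s", paste(dup, collapse = ", "))
  }
  idx <- as.list(names(terms))
  names(idx) <- labs
  idx
}

#' IRI of a registered term
#'
#' OBO-style construction: `<prefix IRI base><PREFIX>_<numeric_id>` when a
#' numeric identifier exists, otherwise a slug IRI
#' `<prefix IRI base><PREFIX>_<local_name>`.
#'
#' @inheritParams register_prefix
#' @param term An [onto_term] or a prefixed token.
#' @return The term IRI as a character scalar.
#' @export
term_iri <- function(registry, term) {
  if (is.character(term)) term <- resolve_term(registry, term)
  base <- registry$env$prefix_table[[term$prefix]]
  if (is.null(base)) {
    ps_stop("phenoscribe_unknown_prefix", "prefix '%s' has no IRI base", term$prefix)
  }
  suffix <- term$numeric_id %||% term$local_name
  paste0(base, term$prefix, "_", suffix)
}

#' Mint a consecutive range of term identifiers
#'
#' Registers `last - first + 1` new terms with consecutive zero-padded 7-digit
#' identifiers, e.g. the block of 25 new skeletomuscular anatomy terms
#' 0000413-0000437 created for the two beetle descriptions. Labels default to
#' placeholders derived from the identifier.
#'
#' @inheritParams register_prefix
#' @param first_id,last_id Zero-padded 7-digit identifier strings with
#'   `first_id <= last_id` numerically.
#' @param local_names Optional local names, one per minted identifier.
#' @param labels Optional labels, one per minted identifier.
#' @return List of the newly registered [onto_term]s, in identifier order.
#' @export
mint_range <- function(registry, prefix, first_id, last_id,
                       local_names = NULL, labels = NULL) {
  for (id in c(first_id, last_id)) {
    if (!grepl("^[0-9]{7}$", id)) {
      ps_stop("phenoscribe_bad_term", "identifier '%s' is not 7 digits", id)
    }
  }
  lo <- as.integer(first_id); hi <- as.integer(last_id)
  if (lo > hi) {
    ps_stop("phenoscribe_range_inverted",
            "inverted identifier range %s-%s", first_id, last_id)
  }
  n <- hi - lo + 1L
  ids <- sprintf("%07d", lo:hi)
  if (!is.null(local_names) && length(local_names) != n) {
    ps_stop("phenoscribe_name_count_mismatch",
            "%d local names supplied for a range of %d identifiers",
            length(local_names), n)
  }
  if (!is.null(labels) && length(labels) != n) {
    ps_stop("phenoscribe_name_count_mismatch",
            "%d labels supplied for a range of %d identifiers", length(labels), n)
  }
  # collision check up front so minting is all-or-nothing
  existing <- vapply(registry$env$terms, function(t) {
    identical(t$prefix, toupper(prefix)) && !is.null(t$numeric_id)
  }, logical(1))
  taken <- vapply(registry$env$terms[existing], function(t) t$numeric_id, character(1))
  clash <- intersect(ids, taken)
  if (length(clash)) {
    ps_stop("phenoscribe_term_collision",
            "identifier(s) already minted: %s", paste(clash, collapse = ", "))
  }
  local_names <- local_names %||% paste0("term_", ids)
  labels <- labels %||% paste(toupper(prefix), ids, "(unlabelled)")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- register_term(registry, prefix, local_names[[i]],
                              label = labels[[i]], numeric_id = ids[[i]])
  }
  out
}

homology_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

as_term_key <- function(registry, x) {
  if (inherits(x, "onto_term")) x <- render_token(x)
  term <- resolve_term(registry, x)
  term_key(term$prefix, term$local_name)
}

#' Record a homology relationship between two registered terms
#'
#' The relation is symmetric: a pair registered as `(a, b)` is retrievable as
#' `(b, a)`. Used e.g. to keep track of the homology between non-articulated
#' tibial spines and the tibial spurs of related species.
#'
#' @inheritParams register_prefix
#' @param a,b Registered terms (objects or tokens).
#' @return The registry, invisibly.
#' @export
register_homology <- function(registry, a, b) {
  ka <- as_term_key(registry, a)
  kb <- as_term_key(registry, b)
  key <- homology_key(ka, kb)
  if (!key %in% registry$env$homologies) {
    registry$env$homologies <- c(registry$env$homologies, key)
  }
  invisible(registry)
}

#' Query the homology store
#'
#' @inheritParams register_homology
#' @return `TRUE` if the pair was registered (in either order).
#' @export
homology_known <- function(registry, a, b) {
  key <- homology_key(as_term_key(registry, a), as_term_key(registry, b))
  key %in% registry$env$homologies
}

#' All homology records
#'
#' @inheritParams register_prefix
#' @return Data frame with columns `term_a` and `term_b` (term keys).
#' @export
homology_pairs <- function(registry) {
  if (!length(registry$env$homologies)) {
    return(data.frame(term_a = character(), term_b = character()))
  }
  parts <- strsplit(registry$env$homologies, "|", fixed = TRUE)
  data.frame(term_a = vapply(parts, `[`, character(1), 1),
             term_b = vapply(parts, `[`, character(1), 2))
}

#' Read a registry from a YAML vocabulary file
#'
#' The file holds a `prefixes` mapping (PREFIX -> IRI base) and a `terms`
#' list; each term entry has `prefix`, `local`, and optionally `label`, `id`,
#' `definition` and `relation`.
#'
#' @param path Path to the vocabulary file.
#' @return A [term_registry()].
#' @export
read_registry <- function(path) {
  doc <- yaml::read_yaml(path)
  reg <- term_registry(unlist(doc$prefixes))
  for (t in doc$terms) {
    register_term(reg, t$prefix, t$local, label = t$label,
                  numeric_id = if (!is.null(t$id)) as.character(t$id),
                  definition = t$definition, relation = isTRUE(t$relation))
  }
  for (h in doc$homologies) {
    register_homology(reg, h[[1]], h[[2]])
  }
  reg
}

#' Write a registry to a YAML vocabulary file
#'
#' @inheritParams register_prefix
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  terms <- lapply(registry$env$terms, function(t) {
    out <- list(prefix = t$prefix, local = t$local_name, label = t$label)
    if (!is.null(t$numeric_id)) out$id <- t$numeric_id
    if (!is.null(t$definition)) out$definition <- t$definition
    if (t$relation) out$relation <- TRUE
    out
  })
  names(terms) <- NULL
  hp <- homology_pairs(registry)
  doc <- list(prefixes = as.list(registry$env$prefix_table), terms = terms)
  if (nrow(hp)) {
    doc$homologies <- lapply(seq_len(nrow(hp)), function(i) {
      as_tokens <- function(k) {
        p <- strsplit(k, ":", fixed = TRUE)[[1]]
        paste0(tolower(p[1]), "-", p[2])
      }
      list(as_tokens(hp$term_a[i]), as_tokens(hp$term_b[i]))
    })
  }
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Seeded registry covering the bundled beetle descriptions
#'
#' Loads the vocabulary shipped with the package: every anatomical entity,
#' quality, relation and unit term used by the two transcribed *Scarabaeus*
#' male descriptions, plus the internal predicate vocabulary used by the
#' graph compiler.
#'
#' @return A [term_registry()].
#' @export
seed_registry <- function() {
  read_registry(ps_example("vocabulary.yml"))
}

#' List registered relation terms
#'
#' @inheritParams register_prefix
#' @return List of [onto_term]s flagged as relations.
#' @export
relation_terms <- function(registry) {
  Filter(function(t) t$relation, registry$env$terms)
}
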