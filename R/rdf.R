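# Minimal RDF machinery: a triple table, deterministic writers for Turtle,
# N-Triples and TriG, and a reader for the (standard-conformant) subset the
# writers emit. No installed R package provides RDF handling, so this is
# implemented here; instance nodes are skolem IRIs derived from canonical
# entity paths, so no blank nodes ever occur and graph isomorphism reduces to
# set equality of expanded triples.

RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
RDF_VALUE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#value"
RDFS_LABEL <- "http://www.w3.org/2000/01/rdf-schema#label"
XSD_DECIMAL <- "http://www.w3.org/2001/XMLSchema#decimal"
XSD_DATETIME <- "http://www.w3.org/2001/XMLSchema#dateTime"

STANDARD_PREFIXES <- c(
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  xsd = "http://www.w3.org/2001/XMLSchema#"
)

empty_triples <- function() {
  data.frame(graph = character(), s = character(), p = character(),
             o = character(), o_kind = character(), dt = character(),
             stringsAsFactors = FALSE)
}

#' Create an empty RDF graph
#'
#' @param prefixes Named character vector of prefix -> IRI base pairs used
#'   when compacting Turtle/TriG output; the standard `rdf`, `rdfs` and `xsd`
#'   prefixes are always included.
#' @return An object of class `rdf_graph` with a `triples` data frame
#'   (columns `graph`, `s`, `p`, `o`, `o_kind`, `dt`) and a `prefixes` map.
#' @export
rdf_graph <- function(prefixes = character()) {
  pf <- c(STANDARD_PREFIXES, prefixes)
  pf <- pf[!duplicated(names(pf))]
  structure(list(triples = empty_triples(), prefixes = pf),
            class = "rdf_graph")
}

add_triple <- function(g, s, p, o, o_kind = "iri", dt = "", graph = "") {
  g$triples <- rbind(g$triples, data.frame(
    graph = graph, s = s, p = p, o = o, o_kind = o_kind, dt = dt,
    stringsAsFactors = FALSE))
  g
}

#' @export
print.rdf_graph <- function(x, ...) {
  cat(sprintf("<rdf_graph> %d triples, %d prefixes\n",
              nrow(x$triples), length(x$prefixes)))
  invisible(x)
}

canonical_triples <- function(g) {
  t <- g$triples
  t <- t[order(t$graph, t$s, t$p, t$o_kind, t$o, t$dt), , drop = FALSE]
  rownames(t) <- NULL
  t
}

#' Number of triples in a graph
#' @param graph An `rdf_graph`.
#' @return Integer triple count.
#' @export
n_triples <- function(graph) nrow(graph$triples)

#' Test two graphs for isomorphism
#'
#' The package never emits blank nodes (instance nodes are skolem IRIs), so
#' isomorphism is set equality of the canonicalized triple tables.
#'
#' @param a,b `rdf_graph` objects.
#' @return `TRUE` or `FALSE`.
#' @export
graph_isomorphic <- function(a, b) {
  isTRUE(all.equal(canonical_triples(a), canonical_triples(b),
                   check.attributes = FALSE))
}

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[[i]], "", fixed = TRUE)[[1]]
    buf <- character(0); j <- 1
    while (j <= length(chars)) {
      if (chars[j] == "\\" && j < length(chars)) {
        nxt <- chars[j + 1]
        buf <- c(buf, switch(nxt, n = "\n", r = "\r", t = "\t",
                             "\\" = "\\", "\"" = "\"", nxt))
        j <- j + 2
      } else {
        buf <- c(buf, chars[j]); j <- j + 1
      }
    }
    out[i] <- paste(buf, collapse = "")
  }
  out
}

compact_iri <- function(iri, prefixes) {
  for (pfx in names(prefixes)) {
    base <- prefixes[[pfx]]
    if (startsWith(iri, base)) {
      local <- substring(iri, nchar(base) + 1)
      # only compact when the local part is a safe prefixed-name local part
      if (grepl("^[A-Za-z0-9_][A-Za-z0-9_.-]*$", local) && !endsWith(local, ".")) {
        return(paste0(pfx, ":", local))
      }
    }
  }
  paste0("<", iri, ">")
}

format_term_iri <- function(iri, prefixes = NULL) {
  if (is.null(prefixes)) paste0("<", iri, ">") else compact_iri(iri, prefixes)
}

format_object <- function(o, o_kind, dt, prefixes = NULL) {
  if (o_kind == "iri") return(format_term_iri(o, prefixes))
  lit <- paste0("\"", escape_literal(o), "\"")
  if (nzchar(dt)) lit <- paste0(lit, "^^", format_term_iri(dt, prefixes))
  lit
}

#' Serialize an RDF graph
#'
#' Output is deterministic (stable node naming and triple ordering): the same
#' graph serializes to byte-identical text. Named graphs are emitted only by
#' the TriG dialect; serializing a graph with named-graph triples to Turtle or
#' N-Triples flattens them into the default graph.
#'
#' @param graph An `rdf_graph`.
#' @param dialect One of `"turtle"`, `"ntriples"`, `"trig"`.
#' @return Serialized document text.
#' @export
serialize_graph <- function(graph, dialect = c("turtle", "ntriples", "trig")) {
  if (!dialect[1] %in% c("turtle", "ntriples", "trig")) {
    ps_stop("phenoscribe_unsupported_dialect",
            "unsupported RDF dialect '%s'", dialect[1])
  }
  dialect <- dialect[1]
  t <- canonical_triples(graph)
  if (dialect == "ntriples") {
    lines <- sprintf("%s %s %s .",
                     format_term_iri(t$s), format_term_iri(t$p),
                     mapply(format_object, t$o, t$o_kind, t$dt,
                            MoreArgs = list(prefixes = NULL)))
    return(paste0(paste(lines, collapse = "\n"),
                  if (length(lines)) "\n" else ""))
  }
  pf <- graph$prefixes[order(names(graph$prefixes))]
  header <- sprintf("@prefix %s: <%s> .", names(pf), unname(pf))
  triple_lines <- function(tt, indent = "") {
    if (!nrow(tt)) return(character())
    sprintf("%s%s %s %s .", indent,
            vapply(tt$s, compact_iri, character(1), prefixes = pf),
            vapply(tt$p, compact_iri, character(1), prefixes = pf),
            mapply(format_object, tt$o, tt$o_kind, tt$dt,
                   MoreArgs = list(prefixes = pf)))
  }
  if (dialect == "turtle") {
    body <- triple_lines(t)
    return(paste0(paste(c(header, "", body), collapse = "\n"), "\n"))
  }
  # trig
  chunks <- character()
  default <- t[t$graph == "", , drop = FALSE]
  chunks <- c(chunks, triple_lines(default))
  for (gname in sort(unique(t$graph[t$graph != ""]))) {
    gg <- t[t$graph == gname, , drop = FALSE]
    chunks <- c(chunks, paste0(compact_iri(gname, pf), " {"),
                triple_lines(gg, indent = "  "), "}")
  }
  paste0(paste(c(header, "", chunks), collapse = "\n"), "\n")
}

# ---- parsing -----------------------------------------------------------------

tokenize_rdf <- function(text) {
  tokens <- list()
  i <- 1; n <- nchar(text)
  push <- function(type, value) tokens[[length(tokens) + 1L]] <<- list(type = type, value = value)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("[[:space:]]", ch)) { i <- i + 1; next }
    if (ch == "#") {
      while (i <= n && substr(text, i, i) != "\n") i <- i + 1
      next
    }
    if (ch == "<") {
      j <- regexpr(">", substr(text, i + 1, n), fixed = TRUE)
      if (j < 0) ps_stop("phenoscribe_rdf_parse", "unterminated IRI at offset %d", i)
      push("iri", substr(text, i + 1, i + j - 1))
      i <- i + j + 1
      next
    }
    if (ch == "\"") {
      j <- i + 1; buf <- ""
      repeat {
        if (j > n) ps_stop("phenoscribe_rdf_parse", "unterminated literal at offset %d", i)
        cj <- substr(text, j, j)
        if (cj == "\\") { buf <- paste0(buf, substr(text, j, j + 1)); j <- j + 2; next }
        if (cj == "\"") break
        buf <- paste0(buf, cj); j <- j + 1
      }
      push("literal", unescape_literal(buf))
      i <- j + 1
      if (substr(text, i, i + 1) == "^^") { push("dtmark", "^^"); i <- i + 2 }
      next
    }
    if (ch %in% c(".", "{", "}")) {
      push(switch(ch, "." = "dot", "{" = "lbrace", "}" = "rbrace"), ch)
      i <- i + 1
      next
    }
    # a word: prefixed name, @prefix keyword, ... — the writers always
    # space-separate the statement terminator ".", so dots inside words
    # (skolem local parts) are safe to swallow
    m <- regexpr("^[^[:space:]<\"{}]+", substr(text, i, n))
    word <- regmatches(substr(text, i, n), m)
    if (!nzchar(word)) ps_stop("phenoscribe_rdf_parse", "cannot tokenize at offset %d", i)
    push("word", word)
    i <- i + nchar(word)
  }
  tokens
}

#' Parse an RDF document
#'
#' Reads the Turtle / N-Triples / TriG subset emitted by [serialize_graph()]
#' (`@prefix` declarations, prefixed names or full IRIs, plain and typed
#' literals, one named-graph block per graph). `parse_rdf(serialize_graph(g))`
#' is isomorphic to `g`.
#'
#' @param text Document text.
#' @param dialect One of `"turtle"`, `"ntriples"`, `"trig"`.
#' @return An `rdf_graph`.
#' @export
parse_rdf <- function(text, dialect = c("turtle", "ntriples", "trig")) {
  if (!dialect[1] %in% c("turtle", "ntriples", "trig")) {
    ps_stop("phenoscribe_unsupported_dialect",
            "unsupported RDF dialect '%s'", dialect[1])
  }
  dialect <- dialect[1]
  toks <- tokenize_rdf(text)
  prefixes <- character()
  expand <- function(tok) {
    if (tok$type == "iri") return(tok$value)
    if (tok$type != "word") {
      ps_stop("phenoscribe_rdf_parse", "expected IRI or prefixed name, got '%s'",
              tok$value)
    }
    parts <- regmatches(tok$value, regexec("^([A-Za-z][A-Za-z0-9_-]*):(.*)$", tok$value))[[1]]
    if (length(parts) == 0) {
      ps_stop("phenoscribe_rdf_parse", "malformed prefixed name '%s'", tok$value)
    }
    if (!parts[2] %in% names(prefixes)) {
      ps_stop("phenoscribe_rdf_parse", "undeclared prefix '%s'", parts[2])
    }
    paste0(prefixes[[parts[2]]], parts[3])
  }
  g <- rdf_graph()
  rows <- list()
  current_graph <- ""
  i <- 1
  take <- function() {
    if (i > length(toks)) {
      ps_stop("phenoscribe_rdf_parse", "unexpected end of document")
    }
    tok <- toks[[i]]; i <<- i + 1
    tok
  }
  peek <- function() if (i <= length(toks)) toks[[i]] else NULL
  while (i <= length(toks)) {
    tok <- peek()
    if (tok$type == "word" && tok$value %in% c("@prefix", "PREFIX")) {
      i <- i + 1
      nm <- take(); iri <- take()
      if (nm$type != "word" || !grepl(":$", nm$value) || iri$type != "iri") {
        ps_stop("phenoscribe_rdf_parse", "malformed @prefix declaration")
      }
      prefixes[[sub(":$", "", nm$value)]] <- iri$value
      if (!is.null(peek()) && peek()$type == "dot") i <- i + 1
      next
    }
    if (tok$type == "rbrace") { current_graph <- ""; i <- i + 1; next }
    # graph block start? term followed by "{"
    if (dialect == "trig" && i + 1 <= length(toks) &&
        toks[[i + 1]]$type == "lbrace" && tok$type %in% c("iri", "word")) {
      current_graph <- expand(tok)
      i <- i + 2
      next
    }
    s <- expand(take())
    p <- expand(take())
    otok <- take()
    if (otok$type == "literal") {
      dt <- ""
      if (!is.null(peek()) && peek()$type == "dtmark") {
        i <- i + 1
        dt <- expand(take())
      }
      rows[[length(rows) + 1L]] <- data.frame(
        graph = current_graph, s = s, p = p, o = otok$value,
        o_kind = "literal", dt = dt, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        graph = current_graph, s = s, p = p, o = expand(otok),
        o_kind = "iri", dt = "", stringsAsFactors = FALSE)
    }
    endtok <- peek()
    if (!is.null(endtok) && endtok$type == "dot") {
      i <- i + 1
    } else if (!is.null(endtok) && endtok$type != "rbrace") {
      ps_stop("phenoscribe_rdf_parse", "expected '.' after triple near '%s'",
              endtok$value)
    }
  }
  if (length(rows)) g$triples <- do.call(rbind, rows)
  for (nm in names(prefixes)) g$prefixes[[nm]] <- prefixes[[nm]]
  g
}
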