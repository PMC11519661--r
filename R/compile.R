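# Compilation of a semantic description into a typed RDF instance graph.
#
# Instance-based EQ modeling: every distinct canonical entity path gets
# exactly one skolem-IRI instance node typed by its ontology class and
# labelled; consecutive path steps are linked child -> parent with part-of.
# Qualities become instance nodes typed by the quality class and linked from
# their bearer with an internal has-quality predicate; relational statements
# become direct edges; comparisons and measurements become reified nodes;
# metadata hangs off a description node. All predicate IRIs derive from the
# registry prefix table (the internal `PHEN` namespace holds placeholders for
# predicates whose canonical IRIs the source vocabulary does not fix).

DEFAULT_BASE_IRI <- "https://w3id.org/phenoscribe/instance/"

path_slug <- function(tokens) {
  paste(sub(sprintf("^[A-Za-z][A-Za-z0-9]*-"), "", tokens), collapse = ".")
}

phen_iri <- function(registry, local) term_iri(registry, paste0("phen-", local))

#' Compile a description into a phenotype graph
#'
#' @param desc A validated [semantic_description()].
#' @param registry A [term_registry()].
#' @param base_iri Base IRI under which skolem instance nodes are minted.
#' @return An object of class `phenotype_graph` (also an `rdf_graph`) with a
#'   `node_table` attribute mapping canonical entity paths to instance IRIs.
#' @export
compile_description <- function(desc, registry, base_iri = DEFAULT_BASE_IRI) {
  issues <- validate_description(desc, registry)
  if (length(issues)) {
    ps_stop("phenoscribe_validation_failed",
            "description does not validate:\n%s",
            paste("-", issues, collapse = "\n"))
  }
  pf <- registry$env$prefix_table
  names(pf) <- tolower(names(pf))
  g <- rdf_graph(c(pf, phsi = base_iri))

  node_table <- character()   # canonical path key -> IRI
  node_tokens <- list()       # canonical path key -> token vector
  node_order <- character()

  ensure_node <- function(tokens) {
    key <- canonical_path(tokens, registry)
    if (!key %in% names(node_table)) {
      if (length(tokens) > 1) ensure_node(tokens[-length(tokens)])
      node_table[[key]] <<- paste0(base_iri, path_slug(tokens))
      node_tokens[[key]] <<- tokens
      node_order <<- c(node_order, key)
    }
    node_table[[key]]
  }

  for (s in desc$statements) {
    kind <- statement_kind(s)
    if (kind %in% c("quality", "relational", "comparative", "measurement")) {
      ensure_node(s$subject)
    }
    if (kind == "relational") ensure_node(s$object)
    if (kind == "comparative") ensure_node(s$reference)
  }

  part_of <- term_iri(registry, "ro-part_of")
  for (key in node_order) {
    tokens <- node_tokens[[key]]
    node <- node_table[[key]]
    cls <- resolve_term(registry, tokens[length(tokens)])
    g <- add_triple(g, node, RDF_TYPE, term_iri(registry, cls))
    g <- add_triple(g, node, RDFS_LABEL, cls$label, o_kind = "literal")
    if (length(tokens) > 1) {
      parent <- node_table[[canonical_path(tokens[-length(tokens)], registry)]]
      g <- add_triple(g, node, part_of, parent)
    }
  }

  has_quality <- phen_iri(registry, "has_quality")
  quality_node <- function(bearer_iri, quality_token) {
    local <- sub("^[A-Za-z][A-Za-z0-9]*-", "", quality_token)
    base <- paste0(bearer_iri, "/q-", local)
    iri <- base; k <- 1
    while (iri %in% g$triples$s) { k <- k + 1; iri <- paste0(base, "-", k) }
    iri
  }
  cmp_counter <- 0L
  desc_node <- paste0(base_iri, "description")
  has_metadata <- FALSE

  for (s in desc$statements) {
    kind <- statement_kind(s)
    if (kind == "quality") {
      bearer <- node_table[[canonical_path(s$subject, registry)]]
      qn <- quality_node(bearer, s$quality)
      g <- add_triple(g, qn, RDF_TYPE, term_iri(registry, s$quality))
      g <- add_triple(g, bearer, has_quality, qn)
    } else if (kind == "relational") {
      subj <- node_table[[canonical_path(s$subject, registry)]]
      obj <- node_table[[canonical_path(s$object, registry)]]
      g <- add_triple(g, subj, term_iri(registry, s$relation), obj)
      if (!is.null(s$attached_quality)) {
        qn <- quality_node(obj, s$attached_quality)
        g <- add_triple(g, qn, RDF_TYPE, term_iri(registry, s$attached_quality))
        g <- add_triple(g, obj, has_quality, qn)
      }
    } else if (kind == "comparative") {
      subj <- node_table[[canonical_path(s$subject, registry)]]
      ref <- node_table[[canonical_path(s$reference, registry)]]
      cmp_counter <- cmp_counter + 1L
      cn <- paste0(subj, "/cmp-", cmp_counter)
      g <- add_triple(g, cn, RDF_TYPE, phen_iri(registry, "comparison"))
      g <- add_triple(g, cn, phen_iri(registry, "comparator"), s$comparator,
                      o_kind = "literal")
      g <- add_triple(g, cn, phen_iri(registry, "subject_attribute"),
                      s$attribute, o_kind = "literal")
      g <- add_triple(g, cn, phen_iri(registry, "reference_attribute"),
                      s$ref_attribute, o_kind = "literal")
      g <- add_triple(g, cn, phen_iri(registry, "comparison_subject"), subj)
      g <- add_triple(g, cn, phen_iri(registry, "comparison_reference"), ref)
    } else if (kind == "measurement") {
      subj <- node_table[[canonical_path(s$subject, registry)]]
      mn <- paste0(subj, "/m-", s$attribute)
      g <- add_triple(g, mn, RDF_TYPE, phen_iri(registry, "measurement"))
      g <- add_triple(g, mn, phen_iri(registry, "measured_attribute"),
                      s$attribute, o_kind = "literal")
      g <- add_triple(g, mn, RDF_VALUE, s$value_text, o_kind = "literal",
                      dt = XSD_DECIMAL)
      g <- add_triple(g, mn, phen_iri(registry, "unit"),
                      term_iri(registry, s$unit))
      g <- add_triple(g, subj, phen_iri(registry, "has_measurement"), mn)
    } else if (kind == "metadata") {
      if (!has_metadata) {
        g <- add_triple(g, desc_node, RDF_TYPE,
                        phen_iri(registry, "semantic_description"))
        has_metadata <- TRUE
      }
      # identifiers become IRI objects (links); the catalog number and plain
      # text values stay literals
      as_iri <- s$key %in% c("taxon_id", "parent_name_usage_id") &&
        is_iri_text(s$value)
      g <- add_triple(g, desc_node, phen_iri(registry, s$key), s$value,
                      o_kind = if (as_iri) "iri" else "literal")
    }
  }
  structure(c(unclass(g), list(node_table = node_table, base_iri = base_iri)),
            class = c("phenotype_graph", "rdf_graph"))
}

#' Node table of a compiled phenotype graph
#'
#' @param graph A `phenotype_graph`.
#' @return Named character vector: canonical entity path -> instance node IRI.
#'   The mapping is a bijection.
#' @export
node_table <- function(graph) graph$node_table

#' @export
print.phenotype_graph <- function(x, ...) {
  cat(sprintf("<phenotype_graph> %d triples, %d instance nodes\n",
              nrow(x$triples), length(x$node_table)))
  invisible(x)
}
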