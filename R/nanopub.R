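# Nanopublication assembly: head / assertion / provenance / pubinfo named
# graphs per the nanopublication guidelines, with fragment-suffixed graph
# URIs. Creation timestamp and creator are explicit arguments so that two
# calls with the same inputs serialize byte-identically.

NP_NS <- "http://www.nanopub.org/nschema#"
PROV_NS <- "http://www.w3.org/ns/prov#"
DCT_NS <- "http://purl.org/dc/terms/"

nanopub_skeleton <- function(uri, registry) {
  pf <- registry$env$prefix_table
  names(pf) <- tolower(names(pf))
  g <- rdf_graph(c(pf, np = NP_NS, prov = PROV_NS, dct = DCT_NS))
  head_g <- paste0(uri, "#Head")
  g <- add_triple(g, uri, RDF_TYPE, paste0(NP_NS, "Nanopublication"), graph = head_g)
  g <- add_triple(g, uri, paste0(NP_NS, "hasAssertion"),
                  paste0(uri, "#assertion"), graph = head_g)
  g <- add_triple(g, uri, paste0(NP_NS, "hasProvenance"),
                  paste0(uri, "#provenance"), graph = head_g)
  g <- add_triple(g, uri, paste0(NP_NS, "hasPublicationInfo"),
                  paste0(uri, "#pubinfo"), graph = head_g)
  g
}

finish_nanopub <- function(g, uri, creator, timestamp) {
  g <- add_triple(g, paste0(uri, "#assertion"),
                  paste0(PROV_NS, "wasAttributedTo"), creator,
                  graph = paste0(uri, "#provenance"))
  g <- add_triple(g, uri, paste0(DCT_NS, "created"), timestamp,
                  o_kind = "literal", dt = XSD_DATETIME,
                  graph = paste0(uri, "#pubinfo"))
  g <- add_triple(g, uri, paste0(DCT_NS, "creator"), creator,
                  graph = paste0(uri, "#pubinfo"))
  structure(c(unclass(g), list(uri = uri)), class = c("nanopub", "rdf_graph"))
}

check_field <- function(value, what) {
  if (is.null(value) || !nzchar(trimws2(value))) {
    ps_stop("phenoscribe_missing_field", "nanopub field '%s' must be non-empty", what)
  }
  invisible(value)
}

name_slug <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))

#' Build a new-taxon-name nanopublication
#'
#' The assertion graph states the new scientific name, its rank, authorship
#' and a link to the parent name usage; provenance attributes the assertion to
#' the creator and pubinfo carries the creation timestamp.
#'
#' @param name Scientific name (e.g. `"Scarabaeus sakalava"`).
#' @param authorship Name authorship string.
#' @param rank Taxonomic rank (e.g. `"species"`).
#' @param parent_usage IRI of the parent name usage.
#' @param creator Creator IRI.
#' @param timestamp ISO-8601 creation timestamp (kept verbatim).
#' @param registry A [term_registry()] supplying the prefix table.
#' @return An object of class `nanopub` (also an `rdf_graph`).
#' @export
build_taxon_nanopub <- function(name, authorship, rank = "species",
                                parent_usage = NULL,
                                creator = "https://w3id.org/phenoscribe/agent",
                                timestamp = "1970-01-01T00:00:00Z",
                                registry = seed_registry()) {
  check_field(name, "name")
  check_field(authorship, "authorship")
  uri <- paste0("https://w3id.org/phenoscribe/np/taxon-name/", name_slug(name))
  g <- nanopub_skeleton(uri, registry)
  a <- paste0(uri, "#assertion")
  nm <- paste0(uri, "#name")
  g <- add_triple(g, nm, RDF_TYPE, phen_iri(registry, "taxon_name"), graph = a)
  g <- add_triple(g, nm, RDFS_LABEL, name, o_kind = "literal", graph = a)
  g <- add_triple(g, nm, phen_iri(registry, "name_authorship"), authorship,
                  o_kind = "literal", graph = a)
  g <- add_triple(g, nm, phen_iri(registry, "taxon_rank"), rank,
                  o_kind = "literal", graph = a)
  if (!is.null(parent_usage)) {
    g <- add_triple(g, nm, phen_iri(registry, "parent_name_usage_id"),
                    parent_usage, graph = a)
  }
  finish_nanopub(g, uri, creator, timestamp)
}

#' Build a taxon-habitat association nanopublication
#'
#' @param taxon Taxon IRI or scientific name.
#' @param habitat_label Habitat described (e.g. `"dry deciduous forest"`).
#' @param evidence_note Optional free-text evidence note.
#' @inheritParams build_taxon_nanopub
#' @return An object of class `nanopub`.
#' @export
build_habitat_nanopub <- function(taxon, habitat_label, evidence_note = NULL,
                                  creator = "https://w3id.org/phenoscribe/agent",
                                  timestamp = "1970-01-01T00:00:00Z",
                                  registry = seed_registry()) {
  check_field(taxon, "taxon")
  check_field(habitat_label, "habitat_label")
  uri <- paste0("https://w3id.org/phenoscribe/np/habitat/", name_slug(taxon))
  g <- nanopub_skeleton(uri, registry)
  a <- paste0(uri, "#assertion")
  taxon_node <- if (is_iri_text(taxon)) taxon else {
    paste0("https://w3id.org/phenoscribe/taxon/", name_slug(taxon))
  }
  if (!is_iri_text(taxon)) {
    g <- add_triple(g, taxon_node, RDFS_LABEL, taxon, o_kind = "literal", graph = a)
  }
  g <- add_triple(g, taxon_node, phen_iri(registry, "has_habitat"),
                  habitat_label, o_kind = "literal", graph = a)
  if (!is.null(evidence_note)) {
    g <- add_triple(g, paste0(uri, "#assertion"),
                    phen_iri(registry, "evidence_note"), evidence_note,
                    o_kind = "literal", graph = a)
  }
  finish_nanopub(g, uri, creator, timestamp)
}

#' Serialize a nanopublication as TriG
#'
#' @param np A `nanopub`.
#' @return TriG text with the head, assertion, provenance and pubinfo named
#'   graphs.
#' @export
serialize_nanopub <- function(np) serialize_graph(np, "trig")

#' Extract one named graph of a nanopublication
#'
#' @param np A `nanopub`.
#' @param which One of `"head"`, `"assertion"`, `"provenance"`, `"pubinfo"`.
#' @return Data frame of the triples in that graph.
#' @export
nanopub_graph <- function(np, which = c("assertion", "head", "provenance", "pubinfo")) {
  which <- match.arg(which)
  gname <- paste0(np$uri, "#", if (which == "head") "Head" else which)
  out <- np$triples[np$triples$graph == gname, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.nanopub <- function(x, ...) {
  cat(sprintf("<nanopub> %s (%d triples)\n", x$uri, nrow(x$triples)))
  invisible(x)
}
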