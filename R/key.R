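# Dichotomous identification keys: couplets of two leads, each lead ending in
# a terminal taxon or pointing to another couplet. The bundled fixture is the
# key to adult Malagasy Scarabaeus (three couplets, four species).

new_lead <- function(text, taxon = NULL, couplet = NULL, figure_refs = NULL) {
  if (is.null(taxon) == is.null(couplet)) {
    ps_stop("phenoscribe_bad_key",
            "a lead must target exactly one of a taxon or a couplet")
  }
  structure(list(text = text, taxon = taxon,
                 couplet = if (!is.null(couplet)) as.integer(couplet),
                 figure_refs = figure_refs),
            class = "key_lead")
}

#' Construct an identification key
#'
#' @param couplets List of couplets; each couplet is a list with an integer
#'   `id` and a `leads` list of exactly two leads (each with `text` and either
#'   `taxon` or `couplet`).
#' @param root_id Identifier of the entry couplet.
#' @param name Optional key title.
#' @return An object of class `taxon_key`.
#' @export
taxon_key <- function(couplets, root_id = 1L, name = "") {
  parsed <- list()
  for (cp in couplets) {
    if (is.null(cp$id)) ps_stop("phenoscribe_bad_key", "couplet without an id")
    id <- as.integer(cp$id)
    if (!is.null(parsed[[as.character(id)]])) {
      ps_stop("phenoscribe_bad_key", "duplicate couplet id %d", id)
    }
    if (length(cp$leads) != 2) {
      ps_stop("phenoscribe_bad_key", "couplet %d must have exactly two leads", id)
    }
    leads <- lapply(cp$leads, function(l) {
      new_lead(l$text %||% "", taxon = l$taxon, couplet = l$couplet,
               figure_refs = l$figure_refs)
    })
    parsed[[as.character(id)]] <- list(id = id, leads = leads)
  }
  structure(list(name = name, root_id = as.integer(root_id), couplets = parsed),
            class = "taxon_key")
}

#' Read an identification key from YAML
#'
#' The file holds `name`, `root`, and a `couplets` list; each couplet has an
#' `id` and two `leads`, each lead with `text`, optional `figure_refs`, and
#' either a terminal `taxon` or a next `couplet` id. In the tabular layout of
#' published keys, lead one is the numbered row and lead two the dash row.
#'
#' @param path Path to the key file.
#' @return A [taxon_key()].
#' @export
read_key <- function(path) {
  doc <- yaml::read_yaml(path)
  taxon_key(doc$couplets, root_id = doc$root %||% 1L, name = doc$name %||% "")
}

#' @export
print.taxon_key <- function(x, ...) {
  cat(sprintf("<taxon_key> %s%d couplets, root %d\n",
              if (nzchar(x$name)) paste0(x$name, ": ") else "",
              length(x$couplets), x$root_id))
  invisible(x)
}

#' Validate the structure of a key
#'
#' Checks that the root couplet exists, every couplet target exists, every
#' couplet is reachable from the root, and no traversal cycles exist.
#'
#' @param key A [taxon_key()].
#' @return Character vector of issues; empty iff the key is structurally
#'   valid.
#' @export
validate_key <- function(key) {
  issues <- character()
  ids <- as.integer(names(key$couplets))
  if (!key$root_id %in% ids) {
    return(sprintf("root couplet %d not present", key$root_id))
  }
  for (cp in key$couplets) {
    for (k in 1:2) {
      tgt <- cp$leads[[k]]$couplet
      if (!is.null(tgt) && !tgt %in% ids) {
        issues <- c(issues, sprintf(
          "couplet %d lead %d targets missing couplet %d", cp$id, k, tgt))
      }
    }
  }
  if (length(issues)) return(issues)
  # reachability and cycle detection by DFS from the root
  state <- new.env(parent = emptyenv())
  state$visited <- integer()
  state$cycle <- FALSE
  dfs <- function(id, trail) {
    if (id %in% trail) { state$cycle <- TRUE; return(invisible()) }
    if (id %in% state$visited) return(invisible())
    state$visited <- c(state$visited, id)
    cp <- key$couplets[[as.character(id)]]
    for (k in 1:2) {
      tgt <- cp$leads[[k]]$couplet
      if (!is.null(tgt)) dfs(tgt, c(trail, id))
    }
  }
  dfs(key$root_id, integer())
  if (state$cycle) issues <- c(issues, "key contains a traversal cycle")
  unreachable <- setdiff(ids, state$visited)
  if (length(unreachable)) {
    issues <- c(issues, sprintf("couplet %d unreachable from root", unreachable))
  }
  issues
}

#' Evaluate a key with an ordered sequence of lead choices
#'
#' Follows the choices from the root couplet; each choice selects lead 1 or
#' lead 2 of the current couplet.
#'
#' @param key A valid [taxon_key()].
#' @param choices Integer vector of 1/2 lead selections.
#' @return The terminal taxon name reached.
#' @export
evaluate_key <- function(key, choices) {
  issues <- validate_key(key)
  if (length(issues)) {
    ps_stop("phenoscribe_bad_key", "invalid key: %s", paste(issues, collapse = "; "))
  }
  id <- key$root_id
  for (i in seq_along(choices)) {
    ch <- choices[[i]]
    if (!ch %in% c(1L, 2L)) {
      ps_stop("phenoscribe_invalid_choice",
              "choice %d is '%s'; each choice must be 1 or 2", i, ch)
    }
    lead <- key$couplets[[as.character(id)]]$leads[[ch]]
    if (!is.null(lead$taxon)) {
      if (i < length(choices)) {
        ps_stop("phenoscribe_invalid_choice",
                "terminal taxon '%s' reached with %d unused choice(s)",
                lead$taxon, length(choices) - i)
      }
      return(lead$taxon)
    }
    id <- lead$couplet
  }
  ps_stop("phenoscribe_choices_exhausted",
          "choices exhausted at couplet %d without reaching a taxon", id)
}

#' Enumerate all terminal taxa of a key
#'
#' @param key A valid [taxon_key()].
#' @return Sorted character vector of the taxa reachable from the root.
#' @export
enumerate_taxa <- function(key) {
  issues <- validate_key(key)
  if (length(issues)) {
    ps_stop("phenoscribe_bad_key", "invalid key: %s", paste(issues, collapse = "; "))
  }
  taxa <- character()
  walk <- function(id) {
    cp <- key$couplets[[as.character(id)]]
    for (k in 1:2) {
      lead <- cp$leads[[k]]
      if (!is.null(lead$taxon)) taxa <<- c(taxa, lead$taxon) else walk(lead$couplet)
    }
  }
  walk(key$root_id)
  sort(unique(taxa))
}
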