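# Memoized fixture loaders: the registry is mutable, so tests that mint or
# register terms must build their own via seed_registry(); read-only tests
# share these.
.fx <- new.env()

fx_registry <- function() {
  if (is.null(.fx$reg)) .fx$reg <- seed_registry()
  .fx$reg
}

fx_desc <- function(species) {
  key <- paste0("desc_", species)
  if (is.null(.fx[[key]])) .fx[[key]] <- example_description(species, fx_registry())
  .fx[[key]]
}

fx_graph <- function(species) {
  key <- paste0("graph_", species)
  if (is.null(.fx[[key]])) {
    .fx[[key]] <- compile_description(fx_desc(species), fx_registry())
  }
  .fx[[key]]
}

signatures <- function(desc) {
  vapply(desc$statements, phenoscribe:::statement_signature, character(1))
}

# normalize whitespace for clause-set comparison
squish <- function(x) gsub("[[:space:]]+", " ", trimws(x))
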