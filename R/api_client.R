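#' @title Repository metadata client
#' @name api_client
#' @description Queries structure-repository APIs (polymer-entity search and
#'   entry data) for entities matching the collection criteria, expands
#'   entities to canonical chains, and assembles chain-level metadata. All
#'   access goes through an injectable transport function so the whole stage
#'   can replay recorded JSON fixtures with no network.
NULL

#' Collection criteria for the entity query
#'
#' Defaults match the dataset collection conditions: X-ray diffraction,
#' resolution at most 3.5 Angstroms, R-free at most 0.33, at most 20
#' (polymer) chains.
#'
#' @param method Experimental method string.
#' @param max_resolution Maximum resolution in Angstroms.
#' @param max_r_free Maximum R-free.
#' @param max_chains Maximum number of polymer chains.
#' @return A `collection_criteria` list.
#' @export
collection_criteria <- function(method = "X-Ray Diffraction",
                                max_resolution = 3.5,
                                max_r_free = 0.33,
                                max_chains = 20) {
  structure(list(method = method, max_resolution = max_resolution,
                 max_r_free = max_r_free, max_chains = max_chains),
            class = "collection_criteria")
}

#' Transport replaying recorded JSON fixtures
#'
#' A transport is a function `(kind, id)` returning a parsed JSON list.
#' This one reads `<kind>_<id>.json` from a directory of recorded responses.
#'
#' @param dir Directory containing fixture files.
#' @return A transport function.
#' @export
fixture_transport <- function(dir) {
  force(dir)
  function(kind, id = "query") {
    path <- file.path(dir, paste0(kind, "_", tolower(id), ".json"))
    if (!file.exists(path)) {
      stop("transport: no recorded response for ", kind, "/", id,
           " (expected ", path, ")")
    }
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
}

#' Query polymer entities matching the collection criteria
#'
#' Every returned entity satisfies all four criteria; a structure with
#' several unique entities yields several records, each expanded to its full
#' set of canonical chain ids. An empty result set is not an error.
#'
#' @param criteria A [collection_criteria()] object.
#' @param transport A transport function (see [fixture_transport()]).
#' @return List of `entity_record` objects with fields `pdb_id`, `entity_id`,
#'   `chain_ids`, `author_chain_map`.
#' @export
query_entities <- function(criteria, transport) {
  stopifnot(inherits(criteria, "collection_criteria"), is.function(transport))
  resp <- transport("entity_search", "query")
  if (is.null(resp$entities)) {
    stop("query_entities: malformed response (no 'entities' element)")
  }
  records <- list()
  for (e in resp$entities) {
    if (!all(c("pdb_id", "entity_id", "chain_ids") %in% names(e))) {
      stop("query_entities: malformed entity record")
    }
    ok <- identical(e$method, criteria$method) &&
      !is.null(e$resolution) && e$resolution <= criteria$max_resolution &&
      !is.null(e$r_free) && e$r_free <= criteria$max_r_free &&
      !is.null(e$num_chains) && e$num_chains <= criteria$max_chains
    if (!ok) next
    acm <- unlist(e$author_chain_map %||% list())
    records[[length(records) + 1]] <- structure(
      list(pdb_id = e$pdb_id, entity_id = as.integer(e$entity_id),
           chain_ids = unlist(e$chain_ids),
           author_chain_map = acm),
      class = "entity_record")
  }
  records
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map an author chain id to its canonical id
#'
#' @param entity An `entity_record`.
#' @param author_id Author chain identifier.
#' @return Canonical chain id (identity when they coincide).
#' @export
map_author_chains <- function(entity, author_id) {
  stopifnot(inherits(entity, "entity_record"))
  if (author_id %in% entity$chain_ids &&
      !(author_id %in% names(entity$author_chain_map))) {
    return(author_id)
  }
  hit <- entity$author_chain_map[[author_id]]
  if (is.null(hit)) {
    stop("unknown author chain id '", author_id, "' for entity ",
         entity$pdb_id, ":", entity$entity_id)
  }
  hit
}

# Table-3 metadata fields fetched from the entry API (computed fields such as
# num_altlocs, num_altloc_segments and cluster_id are filled downstream)
METADATA_API_FIELDS <- c(
  "unp_id", "ena_id", "title", "description", "entity_description",
  "deposition_date", "entity_source_org", "entity_source_org_id",
  "entity_host_org", "entity_host_org_id", "resolution", "resolution_low",
  "r_free", "r_work", "space_group", "cg_ph", "cg_temp", "chain_ligands",
  "ligands", "entity_chains", "entity_auth_chains", "chain_entities",
  "chain_to_auth_chain", "entity_sequence")

#' Fetch chain-level metadata from the entry API
#'
#' Populates the repository-sourced metadata fields for one chain; missing
#' optional annotations (e.g. crystal-growth pH/temperature) become empty
#' values. Chains mapping to zero or more than one UniProt id are flagged for
#' exclusion downstream (`exclude = TRUE`).
#'
#' @param pdb_id Entry identifier.
#' @param chain_id Canonical chain identifier.
#' @param transport A transport function.
#' @return Named list with the metadata fields, plus `pdb_id`
#'   (`"ID:chain"`), `uniprot_ids` and `exclude`.
#' @export
fetch_chain_metadata <- function(pdb_id, chain_id, transport) {
  resp <- transport("entry", pdb_id)
  ch <- resp$chains[[chain_id]]
  if (is.null(ch)) {
    stop("entry ", pdb_id, " has no recorded chain '", chain_id, "'")
  }
  get1 <- function(src, field) {
    v <- src[[field]]
    if (is.null(v) || length(v) == 0) "" else
      if (length(v) > 1) paste(unlist(v), collapse = ";") else v[[1]]
  }
  out <- list(pdb_id = paste0(pdb_id, ":", chain_id))
  for (f in METADATA_API_FIELDS) {
    v <- get1(ch, f)
    if (identical(v, "")) v <- get1(resp, f)
    out[[f]] <- v
  }
  unp <- unlist(ch$uniprot_ids %||% list())
  out$uniprot_ids <- unp
  out$exclude <- length(unp) != 1
  if (length(unp) == 1) out$unp_id <- unp
  out
}
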