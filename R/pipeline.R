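#' @title End-to-end pipeline
#' @name pipeline_cli
#' @description Orchestrates the stages (parse/relabel -> geometry ->
#'   uncertainty -> contacts -> alignment/codons -> quality filter ->
#'   clustering -> segmentation -> emission) over a set of structure files,
#'   with per-chain failure isolation and a run report. A thin command-line
#'   wrapper around [run_pipeline()] ships in `inst/cli/`.
NULL

#' Pipeline configuration
#'
#' @param input_paths Character vector of structure file paths.
#' @param out_dir Output directory for `altloc_data.csv` and
#'   `altloc_metadata.csv`.
#' @param chains Optional named list: file path -> chain ids to process
#'   (default all chains).
#' @param criteria [collection_criteria()] used when querying entities.
#' @param transport Optional transport function for metadata (see
#'   [fixture_transport()]); `NULL` leaves repository metadata empty.
#' @param uniprot_seqs Optional named character vector (UniProt id ->
#'   sequence) for residue indexing.
#' @param cds_sets Optional named list (UniProt id -> character vector of
#'   coding sequences) for codon assignment.
#' @param cutoff_model Optional `resolution_cutoff_model` for the quality
#'   filter; `NULL` with `quality_points` fits one; both absent admits all
#'   chains with a note.
#' @param quality_points Optional data frame (`resolution`, `r_free`) to fit
#'   the cutoff model from.
#' @param contact_threshold Contact distance threshold in Angstroms.
#' @param max_altlocs Altloc label limit for suffixed columns.
#' @param emit_peptide_bonds Also write `peptide_bonds.csv` with
#'   inter-residue C-N distances per altloc pair (schema extension).
#' @param seed Integer seed for any randomized step.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input_paths, out_dir, chains = NULL,
                            criteria = collection_criteria(),
                            transport = NULL, uniprot_seqs = NULL,
                            cds_sets = NULL, cutoff_model = NULL,
                            quality_points = NULL, contact_threshold = 5.0,
                            max_altlocs = 4, emit_peptide_bonds = FALSE,
                            seed = 1L) {
  stopifnot(length(input_paths) > 0, all(file.exists(input_paths)),
            contact_threshold > 0, max_altlocs >= 1)
  structure(list(input_paths = input_paths, out_dir = out_dir,
                 chains = chains, criteria = criteria, transport = transport,
                 uniprot_seqs = uniprot_seqs, cds_sets = cds_sets,
                 cutoff_model = cutoff_model, quality_points = quality_points,
                 contact_threshold = contact_threshold,
                 max_altlocs = max_altlocs,
                 emit_peptide_bonds = emit_peptide_bonds,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full altloc extraction pipeline
#'
#' Parses every input structure, canonicalizes altlocs, computes all
#' per-residue features, applies the R-factor quality filter when the needed
#' inputs are present, clusters the retained chain sequences, and writes the
#' two CSV artifacts. A failure in one chain is logged in the report and
#' skipped, never fatal; zero admissible chains yields header-only outputs
#' with a warning and a successful return.
#'
#' @param config A [pipeline_config()].
#' @return List with `data_path`, `metadata_path`, `data` and `metadata`
#'   data frames, and `report` (per-stage chain counts and per-chain
#'   failures).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(chains_in = 0L, chains_failed = 0L, chains_filtered = 0L,
                 chains_out = 0L, failures = character())
  model <- config$cutoff_model
  if (is.null(model) && !is.null(config$quality_points)) {
    model <- fit_cutoff(config$quality_points)
  }
  contexts <- list()
  for (path in config$input_paths) {
    wanted <- config$chains[[path]]
    chains <- tryCatch(parse_structure(path, chains = wanted),
                       error = function(e) {
                         report$failures <<- c(report$failures, paste0(
                           path, ": ", conditionMessage(e)))
                         NULL
                       })
    if (is.null(chains)) next
    chains <- lapply(chains, relabel_altlocs)
    index <- build_location_index(chains, cell = config$contact_threshold)
    for (chain in chains) {
      if (nrow(chain$residues) == 0) next  # e.g. water-only chains
      tag <- paste0(chain$pdb_id, ":", chain$chain_id)
      report$chains_in <- report$chains_in + 1L
      ctx <- tryCatch(
        build_chain_context(chain, index, config, model),
        error = function(e) {
          report$chains_failed <<- report$chains_failed + 1L
          report$failures <<- c(report$failures,
                                paste0(tag, ": ", conditionMessage(e)))
          NULL
        })
      if (is.null(ctx)) next
      if (isTRUE(ctx$filtered)) {
        report$chains_filtered <- report$chains_filtered + 1L
        next
      }
      contexts[[tag]] <- ctx
    }
  }
  # non-redundant clustering over retained chain sequences
  cluster_ids <- setNames(rep(NA_integer_, length(contexts)), names(contexts))
  if (length(contexts) > 0) {
    seqs <- vapply(contexts, function(c) chain_sequence(c$chain), character(1))
    seqs <- seqs[nzchar(seqs)]
    if (length(seqs) > 0) {
      cl <- cluster_sequences(seqs)
      cluster_ids[names(cl$assignment)] <- cl$assignment
    }
  }
  data_rows <- list(); meta_rows <- list(); bond_rows <- list()
  for (tag in names(contexts)) {
    ctx <- contexts[[tag]]
    data_rows[[tag]] <- assemble_rows(ctx)
    meta_rows[[tag]] <- assemble_metadata_row(
      ctx$chain, meta = ctx$meta, segments = ctx$segments,
      cluster_id = cluster_ids[[tag]])
    if (isTRUE(config$emit_peptide_bonds)) {
      pb <- peptide_bond_lengths(ctx$chain)
      if (nrow(pb) > 0) bond_rows[[tag]] <- cbind(pdb_id = tag, pb)
    }
    report$chains_out <- report$chains_out + 1L
  }
  empty_df <- function(cols) {
    as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  }
  data <- if (length(data_rows) > 0) do.call(rbind, unname(data_rows)) else
    empty_df(data_table_columns())
  meta <- if (length(meta_rows) > 0) do.call(rbind, unname(meta_rows)) else
    empty_df(metadata_table_columns())
  if (report$chains_out == 0) {
    warning("no admissible chains; writing header-only outputs")
  }
  data_path <- file.path(config$out_dir, "altloc_data.csv")
  meta_path <- file.path(config$out_dir, "altloc_metadata.csv")
  write_data_csv(data, data_path)
  write_metadata_csv(meta, meta_path)
  if (isTRUE(config$emit_peptide_bonds) && length(bond_rows) > 0) {
    write.csv(do.call(rbind, unname(bond_rows)),
              file.path(config$out_dir, "peptide_bonds.csv"),
              row.names = FALSE, na = "")
  }
  list(data_path = data_path, metadata_path = meta_path, data = data,
       metadata = meta, report = report)
}

# run the per-chain stages; returns an assemble_rows() context
build_chain_context <- function(chain, index, config, model) {
  meta <- NULL
  if (!is.null(config$transport)) {
    meta <- tryCatch(
      fetch_chain_metadata(chain$pdb_id, chain$chain_id, config$transport),
      error = function(e) NULL)
  }
  if (!is.null(meta)) {
    if (isTRUE(meta$exclude)) {
      return(list(filtered = TRUE))  # zero/multiple UniProt ids
    }
    rw <- suppressWarnings(as.numeric(meta$r_work))
    rf <- suppressWarnings(as.numeric(meta$r_free))
    rs <- suppressWarnings(as.numeric(meta$resolution))
    if (!is.null(model) &&
        !is_admissible(rw, rf, rs, model)) {
      return(list(filtered = TRUE))
    }
  }
  segments <- segment_chain(chain)
  dihedrals <- backbone_dihedrals(chain)
  contacts <- chain_contacts(chain, index, threshold = config$contact_threshold)
  secondary <- suppressWarnings(assign_secondary_structure(chain))
  unp_id <- meta$unp_id %||% ""
  alignment <- NULL; codons <- NULL
  if (nzchar(unp_id) && !is.null(config$uniprot_seqs) &&
      unp_id %in% names(config$uniprot_seqs)) {
    alignment <- align_pair(chain_sequence(chain),
                            config$uniprot_seqs[[unp_id]])
  }
  if (nzchar(unp_id) && !is.null(config$cds_sets) &&
      unp_id %in% names(config$cds_sets)) {
    codons <- assign_codons(chain_sequence(chain), config$cds_sets[[unp_id]])
  }
  list(chain = chain, meta = meta, segments = segments,
       dihedrals = dihedrals, contacts = contacts, secondary = secondary,
       unp_id = unp_id, alignment = alignment, codons = codons,
       max_altlocs = config$max_altlocs, filtered = FALSE)
}
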