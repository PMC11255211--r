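#' @title Dataset assembly and CSV emission
#' @name dataset_emit
#' @description Assembles the per-residue data rows and per-chain metadata
#'   rows and writes the two CSV artifacts (`altloc_data.csv`,
#'   `altloc_metadata.csv`) with a fixed column schema. Altloc-suffixed
#'   columns exist for labels A-D and the six unordered pairs; in-cell lists
#'   use their own delimiters (contacts `,`, altloc names `;`, codon options
#'   `/`) and are protected by CSV quoting.
NULL

ALTLOC_LABELS <- c("A", "B", "C", "D")
ALTLOC_PAIRS <- c("AB", "AC", "AD", "BC", "BD", "CD")

slot_suffix <- function(slot) ifelse(slot == "", "", paste0("_", slot))

#' Column order of the per-residue data table
#' @return Character vector of column names.
#' @export
data_table_columns <- function() {
  per_slot <- function(var) paste0(var, slot_suffix(c("", ALTLOC_LABELS)))
  c("pdb_id", "unp_id", "pdb_idx", "unp_idx", "seg_id", "res_name",
    "res_icode", "res_hflag", "rel_loc", "codon", "codon_score",
    "codon_opts", "secondary",
    unlist(lapply(c("phi", "psi", "omega", "bfactor", "contact_count",
                    "contact_types", "contact_smax", "contact_ooc",
                    "contact_non_aa", "contact_aas"), per_slot)),
    "num_altlocs", "altlocs_N", "altlocs_CA", "altlocs_C",
    paste0("dist_CA_", ALTLOC_PAIRS),
    paste0("dist_CA_", ALTLOC_PAIRS, "_norm"),
    paste0("sigma_CA_", ALTLOC_LABELS),
    "n_terminal_dist", "c_terminal_dist")
}

#' Column order of the per-chain metadata table
#' @return Character vector of column names.
#' @export
metadata_table_columns <- function() {
  c("pdb_id", "unp_id", "ena_id", "seq_len", "num_altlocs", "title",
    "description", "entity_description", "deposition_date",
    "entity_source_org", "entity_source_org_id", "entity_host_org",
    "entity_host_org_id", "resolution", "resolution_low", "r_free",
    "r_work", "space_group", "cg_ph", "cg_temp", "chain_ligands",
    "ligands", "entity_chains", "entity_auth_chains", "chain_entities",
    "chain_to_auth_chain", "entity_sequence", "num_altloc_segments",
    "cluster_id")
}

# render one altloc label set with "(original)" provenance suffixes
render_altloc_names <- function(labels, relabel) {
  if (length(labels) == 0) return("")
  out <- vapply(labels, function(l) {
    if (!is.null(relabel) && l %in% names(relabel)) {
      paste0(l, "(", relabel[[l]], ")")
    } else l
  }, character(1))
  paste(out, collapse = ";")
}

#' Assemble per-residue data rows for one chain
#'
#' One row per chain sequence position, including unmodelled positions
#' inferred from author-numbering gaps (`res_icode = "M"`, geometry columns
#' empty). Altloc labels beyond the limit (default A-D) are dropped from
#' suffixed columns with a warning. All computed stages must be present in
#' the context; annotation stages (alignment, codons, secondary structure)
#' may be absent and yield empty columns.
#'
#' @param ctx List with elements `chain` (a `chain_structure`), `dihedrals`
#'   ([backbone_dihedrals()] output), `contacts` ([chain_contacts()] output),
#'   `segments` ([segment_chain()] output), and optionally `unp_id`,
#'   `alignment` ([align_pair()] result against the UniProt sequence),
#'   `codons` ([assign_codons()] output), `secondary`
#'   ([assign_secondary_structure()] output), `max_altlocs` (default 4).
#' @return Data frame with the [data_table_columns()] schema.
#' @export
assemble_rows <- function(ctx) {
  for (need in c("chain", "dihedrals", "contacts", "segments")) {
    if (is.null(ctx[[need]])) {
      stop("assemble_rows: context is missing stage '", need, "'")
    }
  }
  chain <- ctx$chain
  max_altlocs <- ctx$max_altlocs %||% 4
  labels <- LETTERS[seq_len(max_altlocs)]
  res <- chain$residues
  pres <- altloc_presence(chain)
  seg_id_map <- segment_ids(chain, ctx$segments)
  # full position table: modelled residues plus internal numbering gaps
  positions <- list()
  for (i in seq_len(nrow(res))) {
    if (i > 1 && res$author_seq_num[i] - res$author_seq_num[i - 1] > 1) {
      gap <- seq(res$author_seq_num[i - 1] + 1, res$author_seq_num[i] - 1)
      for (g in gap) {
        positions[[length(positions) + 1]] <- list(modelled = FALSE,
                                                   resno = g, idx = NA)
      }
    }
    positions[[length(positions) + 1]] <- list(modelled = TRUE,
                                               resno = res$author_seq_num[i],
                                               idx = i)
  }
  n_pos <- length(positions)
  n_modelled <- nrow(res)
  all_lab <- unique(unlist(c(pres$altlocs_N, pres$altlocs_CA, pres$altlocs_C)))
  dropped <- setdiff(all_lab, labels)
  if (length(dropped) > 0) {
    warning("chain ", chain$pdb_id, ":", chain$chain_id,
            ": altloc label(s) ", paste(dropped, collapse = ","),
            " beyond the limit of ", max_altlocs,
            " dropped from suffixed columns")
  }
  cols <- data_table_columns()
  template <- setNames(vector("list", length(cols)), cols)
  rows <- vector("list", n_pos)
  modelled_seen <- 0L
  for (p in seq_len(n_pos)) {
    pos <- positions[[p]]
    row <- template
    row$pdb_id <- paste0(chain$pdb_id, ":", chain$chain_id)
    row$unp_id <- ctx$unp_id %||% ""
    row$pdb_idx <- p - 1L
    row$rel_loc <- round(p / n_pos, 3)
    if (!pos$modelled) {
      row$res_icode <- "M"
      row$res_name <- ""
      rows[[p]] <- row
      next
    }
    modelled_seen <- modelled_seen + 1L
    i <- pos$idx
    key <- res$key[i]
    row$res_name <- res$one_letter[i]
    row$res_icode <- if (res$icode[i] != "") res$icode[i] else ""
    row$res_hflag <- res$hetero_flag[i]
    row$seg_id <- seg_id_map[[key]]
    if (!is.null(ctx$alignment)) {
      row$unp_idx <- ctx$alignment$index_map[i]
    }
    if (!is.null(ctx$codons)) {
      row$codon <- ctx$codons$codon[i]
      row$codon_score <- round(ctx$codons$codon_score[i], 3)
      row$codon_opts <- ctx$codons$codon_opts[i]
    }
    if (!is.null(ctx$secondary)) row$secondary <- ctx$secondary[[key]]
    di <- ctx$dihedrals[ctx$dihedrals$key == key, , drop = FALSE]
    for (slot in c("", labels)) {
      sfx <- slot_suffix(slot)
      drow <- di[di$slot == slot, , drop = FALSE]
      if (nrow(drow) == 1) {
        row[[paste0("phi", sfx)]] <- round(drow$phi, 3)
        row[[paste0("psi", sfx)]] <- round(drow$psi, 3)
        row[[paste0("omega", sfx)]] <- round(drow$omega, 3)
      }
      bf <- residue_bfactor(chain, key, if (slot == "") NULL else slot)
      if (!is.na(bf) && (slot == "" || nrow(drow) == 1)) {
        row[[paste0("bfactor", sfx)]] <- round(bf, 3)
      }
      cts <- ctx$contacts[[key]][[if (slot == "") "default" else slot]]
      if (!is.null(cts)) {
        row[[paste0("contact_count", sfx)]] <- cts$contact_count
        row[[paste0("contact_types", sfx)]] <- "proximal"
        row[[paste0("contact_smax", sfx)]] <- cts$contact_smax
        row[[paste0("contact_ooc", sfx)]] <- render_contact_list(cts$ooc)
        row[[paste0("contact_non_aa", sfx)]] <- render_contact_list(cts$non_aa)
        row[[paste0("contact_aas", sfx)]] <- render_contact_list(cts$aas)
      }
    }
    row$num_altlocs <- pres$num_altlocs[i]
    relabel <- chain$relabel_map[[key]]
    row$altlocs_N <- render_altloc_names(
      intersect(pres$altlocs_N[[i]], labels), relabel)
    row$altlocs_CA <- render_altloc_names(
      intersect(pres$altlocs_CA[[i]], labels), relabel)
    row$altlocs_C <- render_altloc_names(
      intersect(pres$altlocs_C[[i]], labels), relabel)
    pd <- ca_pair_distances(chain, key)
    if (nrow(pd) > 0) {
      for (r in seq_len(nrow(pd))) {
        pair <- paste0(pd$X[r], pd$Y[r])
        if (!pair %in% ALTLOC_PAIRS) next
        row[[paste0("dist_CA_", pair)]] <- round(pd$dist[r], 3)
        row[[paste0("dist_CA_", pair, "_norm")]] <- round(pd$dist_norm[r], 3)
      }
    }
    sg <- ca_sigmas(chain, key)
    for (l in intersect(names(sg), labels)) {
      row[[paste0("sigma_CA_", l)]] <- round(sg[[l]], 3)
    }
    row$n_terminal_dist <- modelled_seen - 1L
    row$c_terminal_dist <- n_modelled - modelled_seen
    rows[[p]] <- row
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    r[vapply(r, is.null, logical(1))] <- NA
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[, cols]
}

#' Assemble one per-chain metadata row
#'
#' Combines repository metadata (when available) with the computed chain
#' summaries: sequence length, number of altloc-harboring residues, segment
#' count and cluster id.
#'
#' @param chain A `chain_structure`.
#' @param meta Named list from [fetch_chain_metadata()], or `NULL`.
#' @param segments [segment_chain()] output.
#' @param cluster_id Integer cluster id, or `NA`.
#' @return One-row data frame with the [metadata_table_columns()] schema.
#' @export
assemble_metadata_row <- function(chain, meta = NULL, segments = NULL,
                                  cluster_id = NA) {
  if (is.null(segments)) segments <- segment_chain(chain)
  pres <- altloc_presence(chain)
  cols <- metadata_table_columns()
  row <- setNames(as.list(rep(NA, length(cols))), cols)
  for (f in intersect(names(meta %||% list()), cols)) {
    v <- meta[[f]]
    if (!is.null(v) && length(v) == 1) row[[f]] <- v
  }
  row$pdb_id <- paste0(chain$pdb_id, ":", chain$chain_id)
  ent_seq <- meta$entity_sequence %||% ""
  row$seq_len <- if (nzchar(ent_seq)) nchar(ent_seq) else nrow(chain$residues)
  row$num_altlocs <- sum(pres$num_altlocs > 1)
  row$num_altloc_segments <- nrow(segments)
  row$cluster_id <- cluster_id
  if (is.na(row$chain_to_auth_chain %||% NA)) {
    row$chain_to_auth_chain <- chain$author_chain_id
  }
  as.data.frame(row, stringsAsFactors = FALSE)[, cols]
}

check_schema <- function(rows, expected, what) {
  if (!identical(names(rows), expected)) {
    stop("write_", what, "_csv: column schema mismatch")
  }
}

#' Write the per-residue data CSV
#'
#' RFC-4180 CSV with the exact fixed header; in-cell list delimiters survive
#' because character cells are quoted; undefined values are empty cells.
#'
#' @param rows Data frame from [assemble_rows()] (possibly several chains
#'   row-bound).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_data_csv <- function(rows, path) {
  check_schema(rows, data_table_columns(), "data")
  write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write the per-chain metadata CSV
#' @param rows Data frame from [assemble_metadata_row()] (row-bound).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata_csv <- function(rows, path) {
  check_schema(rows, metadata_table_columns(), "metadata")
  write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}
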