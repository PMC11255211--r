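#' @title Structure parsing and altloc canonicalization
#' @name structure_io
#' @description Functions to read PDB-format coordinate files into per-chain
#'   atom/residue tables with every alternate location retained, canonicalize
#'   non-standard altloc labels, and summarize per-residue altloc presence.
NULL

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O", "OH2")

res_key <- function(resno, icode = "") {
  icode[is.na(icode)] <- ""
  paste0(resno, "|", icode)
}

#' Parse a PDB-format structure file into per-chain tables
#'
#' Reads every ATOM/HETATM record (waters and hydrogens retained but flagged;
#' downstream stages exclude them) and groups records into one
#' `chain_structure` object per chain. All alternate locations are kept;
#' insertion codes are preserved.
#'
#' @param path Path to a PDB-format coordinate file.
#' @param chains Optional character vector of chain identifiers to keep.
#'   Requesting an absent chain is an error listing the available chains.
#' @param pdb_id Optional 4-character entry identifier; defaults to the
#'   file name stem.
#' @return A named list of `chain_structure` objects. Each has elements
#'   `pdb_id`, `chain_id`, `author_chain_id`, `atoms` (one row per atom
#'   location: `author_seq_num`, `icode`, `res_name`, `hetero_flag`,
#'   `atom_name`, `altloc` (blank for single-location atoms),
#'   `original_altloc`, `element`, `x`, `y`, `z`, `occupancy`, `b_factor`,
#'   `is_hydrogen`, `is_water`), `residues` (one row per residue, ordered by
#'   `(author_seq_num, icode)`), and `relabel_map` (filled by
#'   [relabel_altlocs()]).
#' @export
parse_structure <- function(path, chains = NULL, pdb_id = NULL) {
  if (!file.exists(path)) {
    stop("cannot parse structure: file does not exist: ", path)
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, rm.alt = FALSE, rm.insert = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    stop("no ATOM/HETATM records parsed from '", path, "'")
  }
  if (is.null(pdb_id)) {
    pdb_id <- toupper(sub("\\.(pdb|ent)$", "", basename(path)))
  }
  at$chain[is.na(at$chain)] <- " "
  available <- unique(at$chain)
  if (!is.null(chains)) {
    missing <- setdiff(chains, available)
    if (length(missing) > 0) {
      stop("requested chain(s) ", paste(missing, collapse = ", "),
           " not present in ", path, "; available chains: ",
           paste(available, collapse = ", "))
    }
    available <- chains
  }
  out <- lapply(available, function(ch) {
    sub_at <- at[at$chain == ch, , drop = FALSE]
    build_chain_structure(sub_at, pdb_id = pdb_id, chain_id = ch)
  })
  names(out) <- available
  out
}

# assemble a chain_structure from a bio3d atom table subset
build_chain_structure <- function(sub_at, pdb_id, chain_id,
                                  author_chain_id = chain_id) {
  alt <- sub_at$alt
  alt[is.na(alt)] <- ""
  icode <- sub_at$insert
  icode[is.na(icode)] <- ""
  res_name <- sub_at$resid
  is_water <- res_name %in% WATER_NAMES
  elesy <- toupper(trimws(sub_at$elesy))
  elesy[is.na(elesy) | elesy == ""] <- substr(trimws(sub_at$elety[is.na(elesy) | elesy == ""]), 1, 1)
  is_h <- elesy %in% c("H", "D")
  hetero_flag <- ifelse(sub_at$type == "HETATM" & !is_water,
                        paste0("H_", res_name), "")
  atoms <- data.frame(
    author_seq_num = sub_at$resno,
    icode = icode,
    res_name = res_name,
    hetero_flag = hetero_flag,
    atom_name = trimws(sub_at$elety),
    altloc = alt,
    original_altloc = alt,
    element = elesy,
    x = sub_at$x, y = sub_at$y, z = sub_at$z,
    occupancy = ifelse(is.na(sub_at$o), 1, sub_at$o),
    b_factor = ifelse(is.na(sub_at$b), 0, sub_at$b),
    is_hydrogen = is_h,
    is_water = is_water,
    stringsAsFactors = FALSE
  )
  atoms$key <- res_key(atoms$author_seq_num, atoms$icode)
  chain <- structure(
    list(pdb_id = pdb_id, chain_id = chain_id,
         author_chain_id = author_chain_id,
         atoms = atoms, residues = NULL,
         relabel_map = list()),
    class = "chain_structure"
  )
  chain$residues <- residue_table(atoms)
  chain
}

# one row per residue, ordered by (author_seq_num, icode); icode "" first
residue_table <- function(atoms) {
  nonwater <- atoms[!atoms$is_water, , drop = FALSE]
  if (nrow(nonwater) == 0) {
    return(data.frame(key = character(), author_seq_num = integer(),
                      icode = character(), res_name = character(),
                      one_letter = character(), hetero_flag = character(),
                      is_modelled = logical(), stringsAsFactors = FALSE))
  }
  first <- !duplicated(nonwater$key)
  res <- nonwater[first, c("key", "author_seq_num", "icode", "res_name",
                           "hetero_flag"), drop = FALSE]
  res$one_letter <- one_letter_code(res$res_name)
  res$is_modelled <- TRUE
  ord <- order(res$author_seq_num, res$icode, method = "radix")
  res <- res[ord, c("key", "author_seq_num", "icode", "res_name",
                    "one_letter", "hetero_flag", "is_modelled")]
  rownames(res) <- NULL
  res
}

#' Three-letter to one-letter residue code with 'X' fallback
#' @param res_name Character vector of 3-letter component codes.
#' @return Character vector of single letters; unknown components map to "X".
#' @export
one_letter_code <- function(res_name) {
  out <- suppressWarnings(bio3d::aa321(res_name))
  out[is.na(out) | nchar(out) != 1] <- "X"
  out
}

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("<chain_structure %s:%s  %d residues, %d atom locations>\n",
              x$pdb_id, x$chain_id, nrow(x$residues), nrow(x$atoms)))
  invisible(x)
}

# atom rows of one residue
residue_atoms <- function(chain, key) {
  chain$atoms[chain$atoms$key == key & !chain$atoms$is_water, , drop = FALSE]
}

#' Canonicalize non-standard altloc labels
#'
#' Deposited structures occasionally use altloc labels other than the
#' conventional prefix of `A, B, C, ...` (for example a lone `Z`). For every
#' residue whose set of non-blank labels is not such a prefix, labels are
#' sorted lexicographically (raw character order) and reassigned from `'A'`.
#' The original label is retained per atom (`original_altloc`) and per residue
#' in `relabel_map`, so emitters can render provenance as e.g. `"A(Z)"`.
#' Residues with standard labels pass through unchanged. Relabeling is
#' idempotent and never alters coordinates, occupancies or B-factors.
#'
#' @param chain A `chain_structure`.
#' @return The chain with canonical `altloc` labels and a populated
#'   `relabel_map` (named list: residue key -> named character vector mapping
#'   canonical label to original label).
#' @export
relabel_altlocs <- function(chain) {
  stopifnot(inherits(chain, "chain_structure"))
  atoms <- chain$atoms
  relabel_map <- list()
  for (key in unique(atoms$key[!atoms$is_water])) {
    idx <- which(atoms$key == key & !atoms$is_water)
    labels <- sort(unique(atoms$original_altloc[idx][atoms$original_altloc[idx] != ""]),
                   method = "radix")
    if (length(labels) == 0) next
    canonical <- LETTERS[seq_along(labels)]
    if (identical(labels, canonical)) {
      atoms$altloc[idx] <- atoms$original_altloc[idx]
      next
    }
    map <- setNames(labels, canonical)
    relabel_map[[key]] <- map
    old <- atoms$original_altloc[idx]
    new <- old
    nz <- old != ""
    new[nz] <- canonical[match(old[nz], labels)]
    atoms$altloc[idx] <- new
  }
  chain$atoms <- atoms
  chain$relabel_map <- relabel_map
  chain
}

# labels (canonical, non-blank) present on a given atom name of a residue
atom_altlocs <- function(res_atoms, atom_name) {
  labs <- res_atoms$altloc[res_atoms$atom_name == atom_name]
  sort(unique(labs[labs != ""]), method = "radix")
}

#' Per-residue backbone altloc presence
#'
#' Summarizes which altloc labels exist on the backbone N, CA and C atoms of
#' every modelled residue, and the number of distinct labels across those
#' atoms. A residue whose backbone carries only blank (single-location) labels
#' has `num_altlocs = 1`; a missing backbone atom contributes an empty set.
#'
#' @param chain A `chain_structure` (after [relabel_altlocs()]).
#' @return A data frame with one row per modelled residue: `key`,
#'   `author_seq_num`, `icode`, list columns `altlocs_N`, `altlocs_CA`,
#'   `altlocs_C` (canonical labels), and integer `num_altlocs`.
#' @export
altloc_presence <- function(chain) {
  stopifnot(inherits(chain, "chain_structure"))
  res <- chain$residues
  n <- nrow(res)
  aN <- aCA <- aC <- vector("list", n)
  num <- integer(n)
  for (i in seq_len(n)) {
    ra <- residue_atoms(chain, res$key[i])
    aN[[i]]  <- atom_altlocs(ra, "N")
    aCA[[i]] <- atom_altlocs(ra, "CA")
    aC[[i]]  <- atom_altlocs(ra, "C")
    u <- unique(c(aN[[i]], aCA[[i]], aC[[i]]))
    num[i] <- if (length(u) == 0) 1L else length(u)
  }
  out <- res[, c("key", "author_seq_num", "icode")]
  out$altlocs_N <- I(aN)
  out$altlocs_CA <- I(aCA)
  out$altlocs_C <- I(aC)
  out$num_altlocs <- num
  out
}

#' Write chains back to a PDB-format file
#'
#' Minimal fixed-column writer used for round-tripping and for handing
#' structures to external tools. Coordinates are written to 3 decimals,
#' occupancies and B-factors to 2.
#'
#' @param chains A `chain_structure` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(chains, path) {
  if (inherits(chains, "chain_structure")) chains <- list(chains)
  lines <- character()
  serial <- 0L
  for (chain in chains) {
    at <- chain$atoms
    for (i in seq_len(nrow(at))) {
      serial <- serial + 1L
      rec <- if (at$hetero_flag[i] != "" || at$is_water[i]) "HETATM" else "ATOM  "
      nm <- at$atom_name[i]
      nm_field <- if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
      alt <- if (at$altloc[i] == "") " " else at$altloc[i]
      ic <- if (at$icode[i] == "") " " else at$icode[i]
      lines <- c(lines, sprintf(
        "%s%5d %s%s%-3s %1s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        rec, serial %% 100000L, nm_field, alt, at$res_name[i],
        chain$chain_id, at$author_seq_num[i], ic,
        at$x[i], at$y[i], at$z[i], at$occupancy[i], at$b_factor[i],
        at$element[i]))
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
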