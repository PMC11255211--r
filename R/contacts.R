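#' @title Contact detection and classification
#' @name contacts
#' @description Detects all heavy-atom contacts below a distance threshold
#'   (default 5 Angstroms) between each residue's atoms, taken under each of
#'   its altlocs, and every other located atom in the structure; classifies
#'   contacts into same-chain amino-acid (`aas`), other-chain amino-acid
#'   (`ooc`) and non-amino-acid component (`non_aa`) lists; aggregates them
#'   to residue level. Hydrogens and waters are always excluded. A uniform
#'   grid (cell lists at the threshold spacing) accelerates the search; its
#'   result is identical to an exhaustive all-pairs scan.
NULL

#' Build the structure-wide atom location index
#'
#' Collects every location of every non-hydrogen, non-water atom, under every
#' altloc, across all chains (including hetero components). Atoms with a
#' single modelled location carry the pseudo-label `"~"`.
#'
#' @param chains A `chain_structure` or list of them (typically all chains of
#'   one structure).
#' @param cell Grid cell size in Angstroms (defaults to the contact
#'   threshold).
#' @return An `atom_location_index` object: a data frame of entries plus a
#'   hashed grid over positions.
#' @export
build_location_index <- function(chains, cell = 5.0) {
  if (inherits(chains, "chain_structure")) chains <- list(chains)
  parts <- lapply(chains, function(ch) {
    at <- ch$atoms
    at <- at[!at$is_hydrogen & !at$is_water, , drop = FALSE]
    if (nrow(at) == 0) return(NULL)
    data.frame(
      chain_id = ch$chain_id,
      key = at$key,
      author_seq_num = at$author_seq_num,
      res_name = at$res_name,
      hetero_flag = at$hetero_flag,
      atom_name = at$atom_name,
      altloc = ifelse(at$altloc == "", "~", at$altloc),
      x = at$x, y = at$y, z = at$z,
      stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  if (is.null(entries)) {
    entries <- data.frame(chain_id = character(), key = character(),
                          author_seq_num = integer(), res_name = character(),
                          hetero_flag = character(), atom_name = character(),
                          altloc = character(), x = numeric(), y = numeric(),
                          z = numeric(), stringsAsFactors = FALSE)
  }
  rownames(entries) <- NULL
  grid <- new.env(parent = emptyenv())
  if (nrow(entries) > 0) {
    cx <- floor(entries$x / cell); cy <- floor(entries$y / cell)
    cz <- floor(entries$z / cell)
    ckey <- paste(cx, cy, cz, sep = ",")
    split_idx <- split(seq_len(nrow(entries)), ckey)
    for (k in names(split_idx)) assign(k, split_idx[[k]], envir = grid)
  }
  structure(list(entries = entries, grid = grid, cell = cell),
            class = "atom_location_index")
}

# candidate entry rows within one cell-neighbourhood of point p
grid_candidates <- function(index, p) {
  cell <- index$cell
  cx <- floor(p[1] / cell); cy <- floor(p[2] / cell); cz <- floor(p[3] / cell)
  out <- integer(0)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    k <- paste(cx + dx, cy + dy, cz + dz, sep = ",")
    hit <- index$grid[[k]]
    if (!is.null(hit)) out <- c(out, hit)
  }
  out
}

#' Contacts of one residue under one altloc
#'
#' Source atoms are the residue's non-hydrogen, non-water atoms taken at
#' altloc `X` (atoms lacking that label fall back to their default location).
#' Every indexed location outside the source residue is a candidate target;
#' per (target residue, target altloc) the minimum atom-pair distance is
#' kept, and pairs strictly below the threshold are classified:
#' non-amino-acid components (hetero, non-water) in any chain -> `non_aa`;
#' amino acids in the same chain -> `aas`; amino acids in other chains ->
#' `ooc`. Sequence-adjacent residues are not excluded, so covalently bonded
#' neighbours always appear in `aas`.
#'
#' @param chain Source `chain_structure`.
#' @param key Source residue key.
#' @param altloc Source altloc label (`""` or `NULL` for the default slot).
#' @param index An `atom_location_index` over the whole structure.
#' @param threshold Contact distance threshold in Angstroms (default 5.0,
#'   exclusive).
#' @return List with data frames `aas`, `ooc`, `non_aa` (columns `chain_id`,
#'   `name`, `residue_index`, `target_altloc`, `distance`), plus
#'   `contact_count` and `contact_smax` (max same-chain sequence distance,
#'   0 when `aas` is empty).
#' @export
residue_contacts <- function(chain, key, altloc = NULL, index,
                             threshold = 5.0) {
  stopifnot(inherits(index, "atom_location_index"))
  if (is.null(altloc)) altloc <- ""
  ra <- residue_atoms(chain, key)
  ra <- ra[!ra$is_hydrogen, , drop = FALSE]
  src_num <- ra$author_seq_num[1]
  # one source location per atom name: requested label, else default
  best <- list()
  for (nm in unique(ra$atom_name)) {
    p <- atom_coord(ra, nm, if (altloc == "") NULL else altloc)
    if (!is.null(p)) best[[nm]] <- p
  }
  ent <- index$entries
  hits <- new.env(parent = emptyenv())  # target id -> min distance
  for (p in best) {
    cand <- grid_candidates(index, p)
    if (length(cand) == 0) next
    sub <- ent[cand, , drop = FALSE]
    keep <- !(sub$chain_id == chain$chain_id & sub$key == key)
    sub <- sub[keep, , drop = FALSE]
    if (nrow(sub) == 0) next
    d <- sqrt((sub$x - p[1])^2 + (sub$y - p[2])^2 + (sub$z - p[3])^2)
    close <- which(d < threshold)
    for (j in close) {
      id <- paste(sub$chain_id[j], sub$key[j], sub$altloc[j], sep = "\r")
      old <- hits[[id]]
      if (is.null(old) || d[j] < old$distance) {
        hits[[id]] <- list(chain_id = sub$chain_id[j],
                           name = sub$res_name[j],
                           hetero = sub$hetero_flag[j] != "",
                           residue_index = sub$author_seq_num[j],
                           target_altloc = sub$altloc[j],
                           distance = d[j])
      }
    }
  }
  empty <- data.frame(chain_id = character(), name = character(),
                      residue_index = integer(), target_altloc = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  aas <- ooc <- non_aa <- empty
  for (id in ls(hits)) {
    h <- hits[[id]]
    entry <- data.frame(
      chain_id = h$chain_id,
      name = if (h$hetero) h$name else one_letter_code(h$name),
      residue_index = h$residue_index,
      target_altloc = h$target_altloc,
      distance = h$distance, stringsAsFactors = FALSE)
    if (h$hetero) {
      non_aa <- rbind(non_aa, entry)
    } else if (h$chain_id == chain$chain_id) {
      aas <- rbind(aas, entry)
    } else {
      ooc <- rbind(ooc, entry)
    }
  }
  sort_entries <- function(df) {
    if (nrow(df) == 0) return(df)
    df <- df[order(df$chain_id, df$residue_index, df$target_altloc,
                   method = "radix"), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  aas <- sort_entries(aas); ooc <- sort_entries(ooc)
  non_aa <- sort_entries(non_aa)
  smax <- if (nrow(aas) > 0) max(abs(aas$residue_index - src_num)) else 0L
  list(aas = aas, ooc = ooc, non_aa = non_aa,
       contact_count = nrow(aas) + nrow(ooc) + nrow(non_aa),
       contact_smax = as.integer(smax))
}

#' Render a contact list as the published comma-delimited string
#'
#' Each entry renders as `chain_id:residue_name:residue_index:target_altloc:
#' distance` with the distance to two decimals and `"~"` marking
#' single-location targets; entries are ordered by (chain, index, altloc).
#'
#' @param entries Data frame as returned in [residue_contacts()] lists.
#' @return A single string (empty for no contacts).
#' @export
render_contact_list <- function(entries) {
  if (is.null(entries) || nrow(entries) == 0) return("")
  entries <- entries[order(entries$chain_id, entries$residue_index,
                           entries$target_altloc, method = "radix"), ,
                     drop = FALSE]
  paste(sprintf("%s:%s:%d:%s:%.2f", entries$chain_id, entries$name,
                entries$residue_index, entries$target_altloc,
                entries$distance), collapse = ",")
}

#' Contacts for every residue and altloc slot of a chain
#'
#' Convenience driver over [residue_contacts()]: the default slot plus each
#' backbone altloc label of each modelled residue.
#'
#' @param chain A `chain_structure`.
#' @param index An `atom_location_index` over the whole structure.
#' @param threshold Contact threshold in Angstroms.
#' @return Named nested list: `result[[key]][[slot]]` where slot `"default"`
#'   holds the default-location scan; each element as returned by
#'   [residue_contacts()].
#' @export
chain_contacts <- function(chain, index, threshold = 5.0) {
  pres <- altloc_presence(chain)
  out <- list()
  for (i in seq_len(nrow(pres))) {
    key <- pres$key[i]
    labels <- unique(c(pres$altlocs_N[[i]], pres$altlocs_CA[[i]],
                       pres$altlocs_C[[i]]))
    slots <- c("", labels)
    # the default slot is stored under "default" ("" is not addressable as a
    # list name)
    out[[key]] <- setNames(
      lapply(slots, function(s)
        residue_contacts(chain, key, altloc = s, index = index,
                         threshold = threshold)),
      ifelse(slots == "", "default", slots))
  }
  out
}
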