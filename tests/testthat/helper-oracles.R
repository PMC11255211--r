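# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the alignment oracle is a direct Gotoh DP, the
# contact oracle an exhaustive all-pairs scan, the torsion oracle bio3d's
# implementation.

# Affine-gap global alignment score: a gap of length k costs open + k * ext
# (the same convention as the package's aligner). Returns the optimal score.
oracle_align_score <- function(a, b, submat, open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)   # gap in b (consumes a)
  Iy <- matrix(NEG, n + 1, m + 1)   # gap in a (consumes b)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext),
                              Iy[i, j + 1] - (open + ext),
                              Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext),
                              Ix[i + 1, j] - (open + ext),
                              Iy[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

blosum80_matrix <- function() {
  e <- new.env(); utils::data("BLOSUM80", package = "Biostrings", envir = e)
  e$BLOSUM80
}

# Exhaustive all-pairs contact scan over a list of chain_structure objects;
# mirrors the published rule directly: source atoms at the requested altloc
# (default location fallback), every other residue's locations as targets,
# per (target residue, target altloc) minimum, strictly below threshold.
oracle_contacts <- function(chains, src_chain_id, src_key, altloc,
                            threshold = 5) {
  src <- chains[[src_chain_id]]
  sa <- src$atoms[src$atoms$key == src_key & !src$atoms$is_water &
                  !src$atoms$is_hydrogen, , drop = FALSE]
  src_points <- list()
  for (nm in unique(sa$atom_name)) {
    rows <- sa[sa$atom_name == nm, , drop = FALSE]
    pick <- which(rows$altloc == altloc)
    if (length(pick) == 0) pick <- which(rows$altloc == "")
    if (length(pick) == 0) pick <- which(rows$altloc == "A")
    if (length(pick) == 0) pick <- 1
    src_points[[nm]] <- c(rows$x[pick[1]], rows$y[pick[1]], rows$z[pick[1]])
  }
  best <- list()
  for (ch in chains) {
    ta <- ch$atoms[!ch$atoms$is_water & !ch$atoms$is_hydrogen, , drop = FALSE]
    for (r in seq_len(nrow(ta))) {
      if (ch$chain_id == src_chain_id && ta$key[r] == src_key) next
      lab <- if (ta$altloc[r] == "") "~" else ta$altloc[r]
      id <- paste(ch$chain_id, ta$key[r], lab, sep = "/")
      for (p in src_points) {
        d <- sqrt(sum((p - c(ta$x[r], ta$y[r], ta$z[r]))^2))
        if (is.null(best[[id]]) || d < best[[id]]) best[[id]] <- d
      }
    }
  }
  keep <- vapply(best, function(d) d < threshold, logical(1))
  out <- best[keep]
  out[order(names(out))]
}

# flatten a residue_contacts() result to the oracle's id -> distance form
contacts_as_map <- function(rc, chains) {
  entries <- rbind(rc$aas, rc$ooc, rc$non_aa)
  if (nrow(entries) == 0) return(list())
  ids <- character(nrow(entries)); d <- numeric(nrow(entries))
  for (r in seq_len(nrow(entries))) {
    ch <- chains[[entries$chain_id[r]]]
    key <- ch$atoms$key[match(entries$residue_index[r],
                              ch$atoms$author_seq_num)]
    ids[r] <- paste(entries$chain_id[r], key, entries$target_altloc[r],
                    sep = "/")
    d[r] <- entries$distance[r]
  }
  out <- as.list(d)
  names(out) <- ids
  out[order(names(out))]
}

# random structure with 1-2 chains, scattered altlocs, hetero atoms, waters
# and hydrogens, inside a compact box so contacts are plentiful
random_structure <- function(seed, n_res = 12, box = 14) {
  set.seed(seed)
  chain_ids <- if (runif(1) < 0.5) "A" else c("A", "B")
  chains <- lapply(chain_ids, function(cid) {
    rows <- list()
    for (i in seq_len(n_res)) {
      n_alt <- sample(c(1, 1, 2, 3), 1)
      labs <- if (n_alt == 1) "" else LETTERS[seq_len(n_alt)]
      for (atom in c("N", "CA", "C")) {
        base <- runif(3, 0, box)
        for (l in labs) {
          rows[[length(rows) + 1]] <- data.frame(
            author_seq_num = i, icode = "", res_name = "ALA",
            hetero_flag = "", atom_name = atom, altloc = l,
            original_altloc = l, element = if (atom == "N") "N" else "C",
            x = base[1] + runif(1, -0.5, 0.5), y = base[2] + runif(1, -0.5, 0.5),
            z = base[3] + runif(1, -0.5, 0.5),
            occupancy = 1, b_factor = 20, is_hydrogen = FALSE,
            is_water = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
    # a ligand atom, a water and a hydrogen
    extras <- data.frame(
      author_seq_num = c(500L, 600L, 1L), icode = "",
      res_name = c("LIG", "HOH", "ALA"),
      hetero_flag = c("H_LIG", "", ""),
      atom_name = c("C1", "O", "H"),
      altloc = "", original_altloc = "",
      element = c("C", "O", "H"),
      x = runif(3, 0, box), y = runif(3, 0, box), z = runif(3, 0, box),
      occupancy = 1, b_factor = 20,
      is_hydrogen = c(FALSE, FALSE, TRUE),
      is_water = c(FALSE, TRUE, FALSE), stringsAsFactors = FALSE)
    at <- rbind(do.call(rbind, rows), extras)
    at$key <- altlocr:::res_key(at$author_seq_num, at$icode)
    structure(list(pdb_id = "RAND", chain_id = cid, author_chain_id = cid,
                   atoms = at, residues = altlocr:::residue_table(at),
                   relabel_map = list()),
              class = "chain_structure")
  })
  names(chains) <- chain_ids
  chains
}

# handcrafted micro-chain builder for unit tests: atoms is a data.frame with
# resno, res_name, atom, altloc, x, y, z, b (optional occupancy/hetero)
tiny_chain <- function(atoms, chain_id = "A", pdb_id = "TINY") {
  at <- data.frame(
    author_seq_num = atoms$resno, icode = "",
    res_name = atoms$res_name %||na% "ALA",
    hetero_flag = atoms$hetero %||na% "",
    atom_name = atoms$atom,
    altloc = atoms$altloc %||na% "",
    original_altloc = atoms$altloc %||na% "",
    element = substr(atoms$atom, 1, 1),
    x = atoms$x, y = atoms$y, z = atoms$z,
    occupancy = atoms$occupancy %||na% 1,
    b_factor = atoms$b %||na% 20,
    is_hydrogen = substr(atoms$atom, 1, 1) == "H",
    is_water = (atoms$res_name %||na% "ALA") %in% c("HOH", "WAT"),
    stringsAsFactors = FALSE)
  at$key <- altlocr:::res_key(at$author_seq_num, at$icode)
  structure(list(pdb_id = pdb_id, chain_id = chain_id,
                 author_chain_id = chain_id, atoms = at,
                 residues = altlocr:::residue_table(at),
                 relabel_map = list()),
            class = "chain_structure")
}

`%||na%` <- function(a, b) if (is.null(a)) b else a

api_fixture_dir <- function() {
  system.file("extdata", "api_fixtures", package = "altlocr")
}
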