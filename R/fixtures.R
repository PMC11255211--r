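#' @title Synthetic structure fixtures with planted ground truth
#' @name synthetic_fixtures
#' @description Generates small PDB-format structure files with known,
#'   planted properties (ideal-geometry backbones with chosen torsions,
#'   altloc segments with chosen displacements, unmodelled gaps, B-factor
#'   plans, ligands, waters, hydrogens) so that every pipeline stage can be
#'   tested without downloading anything. Ground-truth records are computed
#'   analytically from the planted values, never by the modules under test.
NULL

BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N <- 1.329
ANGLE_N_CA_C <- 111.0
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7

# NeRF atom placement: position d with |c-d| = bond, angle(b,c,d) = angle,
# torsion(a,b,c,d) = torsion (degrees)
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180; chi <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(chi),
          bond * sin(th) * sin(chi))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Ideal-geometry backbone coordinates from planted torsions
#'
#' Builds N/CA/C coordinates for `n` residues using standard bond lengths
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 Angstroms) and bond angles, with the
#' given phi/psi/omega torsions, so that dihedral recovery is an exact test.
#'
#' @param n Number of residues.
#' @param phi,psi,omega Torsions in degrees; scalars are recycled.
#'   `phi[1]` and `omega[1]` are unused (no preceding residue).
#' @return List of `n` lists with elements `N`, `CA`, `C` (3-vectors).
#' @export
ideal_backbone <- function(n, phi = -57, psi = -47, omega = 180) {
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)
  res <- vector("list", n)
  N <- c(0, 0, 0)
  CA <- c(BOND_N_CA, 0, 0)
  a <- (180 - ANGLE_N_CA_C) * pi / 180
  C <- CA + BOND_CA_C * c(cos(a), sin(a), 0)
  res[[1]] <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n - 1)) {
    Nn <- place_atom(res[[i]]$N, res[[i]]$CA, res[[i]]$C,
                     BOND_C_N, ANGLE_CA_C_N, psi[i])
    CAn <- place_atom(res[[i]]$CA, res[[i]]$C, Nn,
                      BOND_N_CA, ANGLE_C_N_CA, omega[i + 1])
    Cn <- place_atom(res[[i]]$C, Nn, CAn,
                     BOND_CA_C, ANGLE_N_CA_C, phi[i + 1])
    res[[i + 1]] <- list(N = Nn, CA = CAn, C = Cn)
  }
  res
}

#' Specification of a synthetic structure fixture
#'
#' @param n_residues Number of residues in the chain (author numbering starts
#'   at `start_resno`).
#' @param phi,psi,omega Planted backbone torsions in degrees (recycled).
#' @param altloc_segments Data frame with columns `start`, `end` (author
#'   residue numbers, inclusive) and `dx`, `dy`, `dz` (Angstrom displacement
#'   of the B conformer); segments must be disjoint and may not contain gap
#'   positions.
#' @param gap_positions Author residue numbers left unmodelled.
#' @param b_factor Baseline B-factor (squared Angstroms) for single-location
#'   atoms and altloc A.
#' @param b_factor_B B-factor for altloc B atoms (defaults to `b_factor`).
#' @param res_names Optional vector of 3-letter residue names (recycled;
#'   default `"ALA"`).
#' @param ligands Data frame of planted hetero atoms: columns `code`,
#'   `resno`, `altloc` (`""` for single-location), `atom`, `x`, `y`, `z`.
#' @param waters Data frame of water oxygen positions (`x`, `y`, `z`).
#' @param hydrogens Logical; add one backbone amide hydrogen per residue.
#' @param chain_id,pdb_id,start_resno Identifiers and first residue number.
#' @param seed Integer seed (fixture generation is seed-deterministic).
#' @return A validated `fixture_spec` list.
#' @export
fixture_spec <- function(n_residues, phi = -57, psi = -47, omega = 180,
                         altloc_segments = NULL, gap_positions = integer(),
                         b_factor = 20, b_factor_B = b_factor,
                         res_names = "ALA", ligands = NULL, waters = NULL,
                         hydrogens = FALSE, chain_id = "A", pdb_id = "SYNT",
                         start_resno = 1L, seed = 1L) {
  resnos <- seq(start_resno, length.out = n_residues)
  if (!is.null(altloc_segments) && nrow(altloc_segments) > 0) {
    covered <- integer(0)
    for (s in seq_len(nrow(altloc_segments))) {
      span <- seq(altloc_segments$start[s], altloc_segments$end[s])
      if (!all(span %in% resnos)) {
        stop("fixture_spec: altloc segment outside the chain")
      }
      if (any(span %in% covered)) {
        stop("fixture_spec: overlapping altloc segments")
      }
      if (any(span %in% gap_positions)) {
        stop("fixture_spec: altloc segment contains a gap position")
      }
      covered <- c(covered, span)
    }
  }
  structure(list(n_residues = n_residues, phi = phi, psi = psi, omega = omega,
                 altloc_segments = altloc_segments,
                 gap_positions = as.integer(gap_positions),
                 b_factor = b_factor, b_factor_B = b_factor_B,
                 res_names = res_names, ligands = ligands, waters = waters,
                 hydrogens = hydrogens, chain_id = chain_id, pdb_id = pdb_id,
                 start_resno = as.integer(start_resno),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic structure file with planted ground truth
#'
#' Writes a PDB-format file realizing the spec and returns the ground truth
#' computed analytically from the planted values: expected contiguous altloc
#' segments (runs split at gaps and non-altloc residues), planted torsions,
#' per-residue inter-conformer CA distance and the B-factor plan.
#'
#' @param spec A [fixture_spec()].
#' @param path Output PDB path (a temporary file by default).
#' @return List with `path`, `spec` and `ground_truth` (elements `segments`
#'   data frame with `start`/`end`/`length`, `phi`, `psi`, `omega`,
#'   `d_CA` named vector, `modelled_resnos`).
#' @export
make_structure <- function(spec, path = tempfile(fileext = ".pdb")) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_residues
  resnos <- seq(spec$start_resno, length.out = n)
  phi <- rep_len(spec$phi, n); psi <- rep_len(spec$psi, n)
  omega <- rep_len(spec$omega, n)
  bb <- ideal_backbone(n, phi, psi, omega)
  res_names <- rep_len(spec$res_names, n)
  in_segment <- rep(FALSE, n)
  disp <- matrix(0, n, 3)
  if (!is.null(spec$altloc_segments)) {
    for (s in seq_len(nrow(spec$altloc_segments))) {
      idx <- which(resnos >= spec$altloc_segments$start[s] &
                   resnos <= spec$altloc_segments$end[s])
      in_segment[idx] <- TRUE
      disp[idx, ] <- matrix(c(spec$altloc_segments$dx[s],
                              spec$altloc_segments$dy[s],
                              spec$altloc_segments$dz[s]),
                            length(idx), 3, byrow = TRUE)
    }
  }
  rows <- list()
  add <- function(resno, res_name, atom, altloc, p, occ, b, element,
                  hetero = "", water = FALSE, hydrogen = FALSE) {
    rows[[length(rows) + 1]] <<- data.frame(
      author_seq_num = resno, icode = "", res_name = res_name,
      hetero_flag = hetero, atom_name = atom, altloc = altloc,
      original_altloc = altloc, element = element,
      x = p[1], y = p[2], z = p[3], occupancy = occ, b_factor = b,
      is_hydrogen = hydrogen, is_water = water, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    if (resnos[i] %in% spec$gap_positions) next
    for (atom in c("N", "CA", "C")) {
      p <- bb[[i]][[atom]]
      el <- if (atom == "N") "N" else "C"
      if (in_segment[i]) {
        add(resnos[i], res_names[i], atom, "A", p, 0.5, spec$b_factor, el)
        add(resnos[i], res_names[i], atom, "B", p + disp[i, ], 0.5,
            spec$b_factor_B, el)
      } else {
        add(resnos[i], res_names[i], atom, "", p, 1.0, spec$b_factor, el)
      }
    }
    if (isTRUE(spec$hydrogens)) {
      add(resnos[i], res_names[i], "H", "", bb[[i]]$N + c(0, 0, 1), 1.0,
          spec$b_factor, "H", hydrogen = TRUE)
    }
  }
  if (!is.null(spec$ligands)) {
    for (j in seq_len(nrow(spec$ligands))) {
      lg <- spec$ligands[j, ]
      add(lg$resno, lg$code, lg$atom, lg$altloc,
          c(lg$x, lg$y, lg$z), 1.0, spec$b_factor,
          substr(lg$atom, 1, 1), hetero = paste0("H_", lg$code))
    }
  }
  if (!is.null(spec$waters)) {
    for (j in seq_len(nrow(spec$waters))) {
      add(9000L + j, "HOH", "O", "", c(spec$waters$x[j], spec$waters$y[j],
                                       spec$waters$z[j]),
          1.0, spec$b_factor, "O", water = TRUE)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$key <- res_key(atoms$author_seq_num, atoms$icode)
  chain <- structure(list(pdb_id = spec$pdb_id, chain_id = spec$chain_id,
                          author_chain_id = spec$chain_id, atoms = atoms,
                          residues = residue_table(atoms),
                          relabel_map = list()),
                     class = "chain_structure")
  write_structure_pdb(chain, path)
  modelled <- setdiff(resnos, spec$gap_positions)
  seg_truth <- planted_segments(resnos[in_segment], spec$gap_positions)
  d_ca <- setNames(sqrt(rowSums(disp^2))[in_segment], resnos[in_segment])
  list(path = path, spec = spec,
       ground_truth = list(segments = seg_truth, phi = phi, psi = psi,
                           omega = omega, d_CA = d_ca,
                           modelled_resnos = modelled))
}

# contiguous runs of planted altloc positions, excluding gaps
planted_segments <- function(altloc_resnos, gap_positions) {
  pos <- sort(setdiff(altloc_resnos, gap_positions))
  if (length(pos) == 0) {
    return(data.frame(start = integer(), end = integer(), length = integer()))
  }
  breaks <- c(0, which(diff(pos) > 1), length(pos))
  do.call(rbind, lapply(seq_len(length(breaks) - 1), function(k) {
    run <- pos[(breaks[k] + 1):breaks[k + 1]]
    data.frame(start = run[1], end = run[length(run)], length = length(run))
  }))
}

# reverse standard genetic code: amino acid -> sorted codons
codons_for_aa <- local({
  tab <- NULL
  function(aa) {
    if (is.null(tab)) {
      gc <- Biostrings::GENETIC_CODE
      tab <<- split(names(gc), unname(gc))
      tab <<- lapply(tab, sort, method = "radix")
    }
    tab[[aa]]
  }
})

#' Generate coding sequences with a planted codon agreement level
#'
#' Back-translates a protein `n_seqs` times. At every position a designated
#' codon (the lexicographically smallest for that amino acid) is used by
#' `round(agreement * n_seqs)` of the sequences and a synonymous alternative
#' by the rest; amino acids with a single codon (Met, Trp) are invariant.
#' Which sequences carry the alternative is drawn with the seed, so
#' generation is seed-deterministic.
#'
#' @param protein Amino-acid string (standard 20 letters).
#' @param n_seqs Number of coding sequences.
#' @param agreement Target proportion carrying the designated codon.
#' @param seed Integer seed.
#' @return List with `cds` (character vector of nucleotide sequences) and
#'   `expected` (data frame: `pos`, `codon`, `codon_score`, `codon_opts`).
#' @export
make_cds_set <- function(protein, n_seqs, agreement = 1.0, seed = 1L) {
  aa <- strsplit(protein, "")[[1]]
  k <- round(agreement * n_seqs)
  stopifnot(k >= 1, k <= n_seqs)
  set.seed(seed)
  alt_carriers <- if (n_seqs > k) sample(n_seqs, n_seqs - k) else integer(0)
  seq_codons <- matrix("", nrow = n_seqs, ncol = length(aa))
  exp_codon <- exp_opts <- character(length(aa))
  exp_score <- numeric(length(aa))
  for (i in seq_along(aa)) {
    cods <- codons_for_aa(aa[i])
    if (is.null(cods)) stop("make_cds_set: unknown amino acid '", aa[i], "'")
    designated <- cods[1]
    alt <- if (length(cods) > 1) cods[2] else cods[1]
    seq_codons[, i] <- designated
    seq_codons[alt_carriers, i] <- alt
    exp_codon[i] <- designated
    exp_score[i] <- if (alt == designated) 1 else k / n_seqs
    exp_opts[i] <- if (alt == designated) designated else
      paste(sort(c(designated, alt), method = "radix"), collapse = "/")
  }
  cds <- apply(seq_codons, 1, paste, collapse = "")
  list(cds = cds,
       expected = data.frame(pos = seq_along(aa), codon = exp_codon,
                             codon_score = exp_score, codon_opts = exp_opts,
                             stringsAsFactors = FALSE))
}

#' Synthetic two-chain contact showcase structure
#'
#' A synthetic stand-in structure (planted coordinates, not a deposited
#' entry) realizing a published-style contact topology: a 7-residue altloc
#' segment in chain J (residues 1493-1499, conformer B displaced 2 Angstroms)
#' whose Ser 1497 makes out-of-chain contacts to a two-residue chain I
#' fragment (Tyr 1523 at 3.05 Angstroms, Glu 1524 at 4.32 Angstroms), and
#' whose Trp 1495 contacts a two-conformer K6P ligand (altloc A at 2.54,
#' altloc B at 4.13 Angstroms). A hydrogen and a water are planted near the
#' contacts to exercise their exclusion.
#'
#' @param path Output PDB path.
#' @return List with `path` and `expected`: the exact rendered contact
#'   strings `ooc_A_1497` and `non_aa_B_1495`, plus the four planted
#'   distances.
#' @export
synthetic_contact_showcase <- function(path = tempfile(fileext = ".pdb")) {
  res3 <- c("GLY", "ALA", "TRP", "ALA", "SER", "ALA", "GLY")
  resnos <- 1493:1499
  rows <- list()
  add <- function(resno, res_name, atom, altloc, p, b = 20, chain = "J",
                  element = "C", hetero = "", water = FALSE, hyd = FALSE) {
    rows[[length(rows) + 1]] <<- data.frame(
      chain = chain, author_seq_num = resno, icode = "", res_name = res_name,
      hetero_flag = hetero, atom_name = atom, altloc = altloc,
      original_altloc = altloc, element = element, x = p[1], y = p[2],
      z = p[3], occupancy = if (altloc == "") 1 else 0.5, b_factor = b,
      is_hydrogen = hyd, is_water = water, stringsAsFactors = FALSE)
  }
  for (i in seq_along(resnos)) {
    x0 <- 3.8 * (i - 1)
    for (atom in c("N", "CA", "C")) {
      dx <- c(N = -1.2, CA = 0, C = 1.2)[[atom]]
      el <- if (atom == "N") "N" else "C"
      add(resnos[i], res3[i], atom, "A", c(x0 + dx, 0, 0), element = el)
      add(resnos[i], res3[i], atom, "B", c(x0 + dx, 2, 0), element = el)
    }
  }
  ca_s1497_A <- c(3.8 * 4, 0, 0)
  ca_w1495_B <- c(3.8 * 2, 2, 0)
  add(1523L, "TYR", "CA", "", ca_s1497_A + c(0, 0, 3.05), chain = "I")
  add(1524L, "GLU", "CA", "", ca_s1497_A + c(0, 0, -4.32), chain = "I")
  add(1701L, "K6P", "P1", "A", ca_w1495_B + c(0, 0, 2.54), element = "P",
      hetero = "H_K6P")
  add(1701L, "K6P", "P1", "B", ca_w1495_B + c(0, 0, -4.13), element = "P",
      hetero = "H_K6P")
  add(1493L, "GLY", "H", "", ca_w1495_B + c(0, 0, 1.0), element = "H",
      hyd = TRUE)
  add(9001L, "HOH", "O", "", ca_s1497_A + c(0, 0, 1.5), element = "O",
      water = TRUE)
  df <- do.call(rbind, rows)
  chains <- lapply(c("J", "I"), function(ch) {
    atoms <- df[df$chain == ch, setdiff(names(df), "chain"), drop = FALSE]
    atoms$key <- res_key(atoms$author_seq_num, atoms$icode)
    structure(list(pdb_id = "SHOW", chain_id = ch, author_chain_id = ch,
                   atoms = atoms, residues = residue_table(atoms),
                   relabel_map = list()),
              class = "chain_structure")
  })
  write_structure_pdb(chains, path)
  list(path = path,
       expected = list(
         ooc_A_1497 = "I:Y:1523:~:3.05,I:E:1524:~:4.32",
         non_aa_B_1495 = "J:K6P:1701:A:2.54,J:K6P:1701:B:4.13",
         distances = c(3.05, 4.32, 2.54, 4.13)))
}

#' Synthetic broken-segment structure
#'
#' A synthetic stand-in chain realizing the published broken-segment
#' topology: an altloc region whose B conformer is not modelled between
#' residues 37 and 41 (residues 38-40 are single-conformer), so the region
#' must be counted as two separate segments (33-37 and 41-45).
#'
#' @param path Output PDB path.
#' @return The [make_structure()] result; `ground_truth$segments` has the
#'   two expected runs.
#' @export
synthetic_broken_segment <- function(path = tempfile(fileext = ".pdb")) {
  spec <- fixture_spec(
    n_residues = 19, start_resno = 30L, pdb_id = "BRKN",
    altloc_segments = data.frame(start = c(33, 41), end = c(37, 45),
                                 dx = 0.5, dy = 0, dz = 0))
  make_structure(spec, path)
}
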