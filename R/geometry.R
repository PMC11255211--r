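#' @title Backbone geometry per alternate location
#' @name geometry
#' @description Torsion angles (phi/psi/omega) computed separately for each
#'   altloc with a single-conformer fallback for neighbouring residues,
#'   peptide bond lengths across altloc pairs, and per-residue secondary
#'   structure via DSSP when available.
NULL

#' Signed torsion angle of four points
#'
#' IUPAC-signed dihedral angle, in degrees within `(-180, 180]`. Degenerate
#' geometry (collinear first or last three points, or coincident bonded
#' points) yields `NA` rather than an error.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstroms).
#' @return Angle in degrees in `(-180, 180]`, or `NA` when undefined.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sum(b2 * b2) == 0) return(NA_real_)
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1 * n1) < 1e-12 || sum(n2 * n2) < 1e-12) return(NA_real_)
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb2 <- sqrt(sum(b2 * b2))
  x <- sum(n1 * n2)
  y <- -sum(m1 * n2) / nb2
  ang <- atan2(y, x) * 180 / pi
  # closed at +180, open at -180
  if (ang <= -180) ang <- ang + 360
  ang
}

# coordinate of one atom of a residue under a given altloc label, applying
# the fallback rule: exact label if modelled, else the default location
# (blank-label position when present, otherwise altloc 'A')
atom_coord <- function(res_atoms, atom_name, label = NULL) {
  rows <- res_atoms[res_atoms$atom_name == atom_name, , drop = FALSE]
  if (nrow(rows) == 0) return(NULL)
  if (!is.null(label) && label != "") {
    hit <- rows[rows$altloc == label, , drop = FALSE]
    if (nrow(hit) > 0) return(c(hit$x[1], hit$y[1], hit$z[1]))
  }
  blank <- rows[rows$altloc == "", , drop = FALSE]
  if (nrow(blank) > 0) return(c(blank$x[1], blank$y[1], blank$z[1]))
  a <- rows[rows$altloc == "A", , drop = FALSE]
  if (nrow(a) > 0) return(c(a$x[1], a$y[1], a$z[1]))
  c(rows$x[1], rows$y[1], rows$z[1])
}

# are two modelled residues sequence-adjacent (peptide-bond plausible)?
seq_adjacent <- function(res, i, j) {
  if (is.na(i) || is.na(j) || i < 1 || j > nrow(res)) return(FALSE)
  d <- res$author_seq_num[j] - res$author_seq_num[i]
  d == 1L || (d == 0L && res$icode[i] != res$icode[j])
}

#' Backbone dihedral angles per altloc for every residue of a chain
#'
#' For each modelled residue, phi/psi/omega are computed once with every atom
#' at its default location (the `""` slot, "ignoring altlocs") and once per
#' altloc label present on the residue's backbone. At altloc `X`, atoms of the
#' previous/next residue that do not carry label `X` fall back to their
#' default location. Chain termini and numbering gaps leave the affected
#' angles `NA`. The omega reported for residue `i` is the torsion of the
#' peptide bond arriving at `i`: `CA(i-1), C(i-1), N(i), CA(i)`.
#'
#' @param chain A `chain_structure`.
#' @return Data frame with columns `key`, `slot` (`""` for the default slot or
#'   an altloc label), `phi`, `psi`, `omega` (degrees, `NA` when undefined).
#' @export
backbone_dihedrals <- function(chain) {
  stopifnot(inherits(chain, "chain_structure"))
  res <- chain$residues
  pres <- altloc_presence(chain)
  rows <- list()
  for (i in seq_len(nrow(res))) {
    ra <- residue_atoms(chain, res$key[i])
    prev_ra <- if (i > 1 && seq_adjacent(res, i - 1, i))
      residue_atoms(chain, res$key[i - 1]) else NULL
    next_ra <- if (i < nrow(res) && seq_adjacent(res, i, i + 1))
      residue_atoms(chain, res$key[i + 1]) else NULL
    labels <- unique(c(pres$altlocs_N[[i]], pres$altlocs_CA[[i]],
                       pres$altlocs_C[[i]]))
    for (slot in c("", labels)) {
      lab <- if (slot == "") NULL else slot
      N <- atom_coord(ra, "N", lab); CA <- atom_coord(ra, "CA", lab)
      C <- atom_coord(ra, "C", lab)
      phi <- psi <- omega <- NA_real_
      if (!is.null(prev_ra)) {
        Cp <- atom_coord(prev_ra, "C", lab)
        CAp <- atom_coord(prev_ra, "CA", lab)
        if (!is.null(Cp) && !is.null(N) && !is.null(CA) && !is.null(C))
          phi <- dihedral_angle(Cp, N, CA, C)
        if (!is.null(CAp) && !is.null(Cp) && !is.null(N) && !is.null(CA))
          omega <- dihedral_angle(CAp, Cp, N, CA)
      }
      if (!is.null(next_ra)) {
        Nn <- atom_coord(next_ra, "N", lab)
        if (!is.null(N) && !is.null(CA) && !is.null(C) && !is.null(Nn))
          psi <- dihedral_angle(N, CA, C, Nn)
      }
      rows[[length(rows) + 1]] <- data.frame(
        key = res$key[i], slot = slot, phi = phi, psi = psi, omega = omega,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(key = character(), slot = character(),
                      phi = numeric(), psi = numeric(), omega = numeric()))
  }
  do.call(rbind, rows)
}

#' Peptide bond lengths between adjacent residues under each altloc pair
#'
#' Euclidean distance between the carbonyl carbon of each residue and the
#' backbone nitrogen of the following sequence-adjacent residue, for every
#' pair of locations (blank labels act as single-location slots, reported
#' as `"~"`).
#'
#' @param chain A `chain_structure`.
#' @return Data frame with columns `key`, `next_key`, `altloc_C`, `altloc_N`
#'   (labels or `"~"`), `dist` (Angstroms).
#' @export
peptide_bond_lengths <- function(chain) {
  stopifnot(inherits(chain, "chain_structure"))
  res <- chain$residues
  rows <- list()
  for (i in seq_len(max(nrow(res) - 1, 0))) {
    if (!seq_adjacent(res, i, i + 1)) next
    cur <- residue_atoms(chain, res$key[i])
    nxt <- residue_atoms(chain, res$key[i + 1])
    c_rows <- cur[cur$atom_name == "C", , drop = FALSE]
    n_rows <- nxt[nxt$atom_name == "N", , drop = FALSE]
    if (nrow(c_rows) == 0 || nrow(n_rows) == 0) next
    for (a in seq_len(nrow(c_rows))) {
      for (b in seq_len(nrow(n_rows))) {
        d <- sqrt((c_rows$x[a] - n_rows$x[b])^2 +
                  (c_rows$y[a] - n_rows$y[b])^2 +
                  (c_rows$z[a] - n_rows$z[b])^2)
        rows[[length(rows) + 1]] <- data.frame(
          key = res$key[i], next_key = res$key[i + 1],
          altloc_C = ifelse(c_rows$altloc[a] == "", "~", c_rows$altloc[a]),
          altloc_N = ifelse(n_rows$altloc[b] == "", "~", n_rows$altloc[b]),
          dist = d, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(key = character(), next_key = character(),
                      altloc_C = character(), altloc_N = character(),
                      dist = numeric()))
  }
  do.call(rbind, rows)
}

#' Per-residue secondary structure via DSSP
#'
#' Runs the DSSP executable (`mkdssp` or `dssp`) on a structure file and
#' returns one single-letter label per residue. When the executable is not on
#' the PATH the pipeline degrades gracefully: every label is blank and a
#' warning is issued, but the run succeeds.
#'
#' @param chain A `chain_structure` (written to a temporary file), or a path
#'   to a structure file together with `keys`.
#' @param exefile Optional explicit path to the DSSP executable.
#' @return Named character vector (residue key -> DSSP letter, `""` for
#'   residues DSSP skips or when DSSP is unavailable).
#' @export
assign_secondary_structure <- function(chain, exefile = NULL) {
  stopifnot(inherits(chain, "chain_structure"))
  keys <- chain$residues$key
  blank <- setNames(rep("", length(keys)), keys)
  exe <- exefile
  if (is.null(exe)) {
    for (cand in c("mkdssp", "dssp")) {
      if (nzchar(Sys.which(cand))) { exe <- cand; break }
    }
  }
  if (is.null(exe) || !nzchar(Sys.which(exe))) {
    warning("DSSP executable not found; secondary-structure labels left blank")
    return(blank)
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  write_structure_pdb(chain, tmp)
  ss <- tryCatch({
    pdb <- bio3d::read.pdb(tmp, verbose = FALSE)
    d <- bio3d::dssp(pdb, exefile = exe)
    d
  }, error = function(e) NULL)
  if (is.null(ss) || is.null(ss$sse)) {
    warning("DSSP run failed; secondary-structure labels left blank")
    return(blank)
  }
  helix <- ss$helix; sheet <- ss$sheet
  out <- blank
  fill <- function(ranges, letter) {
    if (is.null(ranges) || length(ranges$start) == 0) return()
    for (j in seq_along(ranges$start)) {
      rng <- seq(ranges$start[j], ranges$end[j])
      hit <- chain$residues$author_seq_num %in% rng
      out[chain$residues$key[hit]] <<- letter
    }
  }
  fill(helix, "H"); fill(sheet, "E")
  out
}
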