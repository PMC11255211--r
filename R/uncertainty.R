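#' @title B-factor-derived positional uncertainty and inter-conformer distances
#' @name uncertainty
#' @description Per-altloc residue B-factors (backbone mean), conversion of
#'   isotropic B-factors to a positional standard deviation via
#'   `sigma = sqrt(B / (8 * pi^2))`, and raw / uncertainty-normalized
#'   distances between the alpha-carbon positions of altloc pairs.
NULL

#' Mean backbone B-factor of a residue at one altloc slot
#'
#' Averages the isotropic B-factors of the N, CA and C atoms. For a specific
#' altloc label, the value is defined only when all three atoms explicitly
#' carry that label; the default slot (`altloc = NULL`) uses each atom's
#' default location (blank label when present, otherwise altloc 'A').
#'
#' @param chain A `chain_structure`.
#' @param key Residue key (see `chain$residues$key`).
#' @param altloc Altloc label, or `NULL` for the default slot.
#' @return Mean B-factor in squared Angstroms, or `NA` when undefined.
#' @export
residue_bfactor <- function(chain, key, altloc = NULL) {
  ra <- residue_atoms(chain, key)
  vals <- numeric(3)
  nms <- c("N", "CA", "C")
  for (k in seq_along(nms)) {
    rows <- ra[ra$atom_name == nms[k], , drop = FALSE]
    if (nrow(rows) == 0) return(NA_real_)
    if (is.null(altloc)) {
      pick <- which(rows$altloc == "")
      if (length(pick) == 0) pick <- which(rows$altloc == "A")
      if (length(pick) == 0) pick <- 1L
    } else {
      pick <- which(rows$altloc == altloc)
      if (length(pick) == 0) return(NA_real_)  # label must exist on all three
    }
    vals[k] <- rows$b_factor[pick[1]]
  }
  mean(vals)
}

#' Positional standard deviation from an isotropic B-factor
#'
#' `sigma = sqrt(B / (8 * pi^2))`, so `B = 8 * pi^2` corresponds to a
#' displacement of exactly 1 Angstrom.
#'
#' @param B Non-negative isotropic B-factor(s) in squared Angstroms.
#' @return Standard deviation(s) in Angstroms.
#' @export
sigma_from_bfactor <- function(B) {
  if (any(!is.na(B) & B < 0)) stop("B-factor must be non-negative")
  sqrt(B / EIGHT_PI_SQ)
}

#' Inter-conformer alpha-carbon distances of one residue
#'
#' For every unordered pair of altloc labels `{X, Y}` modelled for the CA
#' atom: the Euclidean distance `d = ||p_CA,X - p_CA,Y||` and its
#' uncertainty-normalized form `d_norm = d / sqrt(sigma_X * sigma_Y)`, where
#' each sigma derives from the CA atom's own B-factor at that label.
#' `d_norm` is `NA` when either sigma is zero.
#'
#' @param chain A `chain_structure`.
#' @param key Residue key.
#' @return Data frame with columns `X`, `Y` (labels, `X < Y`), `dist`
#'   (Angstroms), `dist_norm` (dimensionless), `sigma_X`, `sigma_Y`
#'   (Angstroms). Empty when the CA atom has fewer than two altlocs.
#' @export
ca_pair_distances <- function(chain, key) {
  ra <- residue_atoms(chain, key)
  ca <- ra[ra$atom_name == "CA" & ra$altloc != "", , drop = FALSE]
  empty <- data.frame(X = character(), Y = character(), dist = numeric(),
                      dist_norm = numeric(), sigma_X = numeric(),
                      sigma_Y = numeric(), stringsAsFactors = FALSE)
  if (nrow(ca) < 2) return(empty)
  ca <- ca[order(ca$altloc, method = "radix"), , drop = FALSE]
  rows <- list()
  for (a in seq_len(nrow(ca) - 1)) {
    for (b in seq((a + 1), nrow(ca))) {
      d <- sqrt((ca$x[a] - ca$x[b])^2 + (ca$y[a] - ca$y[b])^2 +
                (ca$z[a] - ca$z[b])^2)
      sX <- sigma_from_bfactor(ca$b_factor[a])
      sY <- sigma_from_bfactor(ca$b_factor[b])
      dn <- if (sX * sY > 0) d / sqrt(sX * sY) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        X = ca$altloc[a], Y = ca$altloc[b], dist = d, dist_norm = dn,
        sigma_X = sX, sigma_Y = sY, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-altloc CA position standard deviations of one residue
#'
#' @param chain A `chain_structure`.
#' @param key Residue key.
#' @return Named numeric vector (altloc label -> sigma in Angstroms) over the
#'   CA atom's non-blank labels.
#' @export
ca_sigmas <- function(chain, key) {
  ra <- residue_atoms(chain, key)
  ca <- ra[ra$atom_name == "CA" & ra$altloc != "", , drop = FALSE]
  if (nrow(ca) == 0) return(setNames(numeric(0), character(0)))
  setNames(sigma_from_bfactor(ca$b_factor), ca$altloc)
}
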