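#' @title Contiguous altloc segments
#' @name segmentation
#' @description Groups residues harboring backbone altlocs into numbered
#'   contiguous segments. A residue "harbors" an altloc when its CA atom is
#'   modelled in two or more locations. A run interrupted by unmodelled
#'   residues (a numbering gap) or by single-conformer residues splits into
#'   separate segments.
NULL

# does this residue harbor a backbone altloc? (CA with >= 2 locations)
harbors_altloc <- function(chain, key) {
  ra <- residue_atoms(chain, key)
  length(atom_altlocs(ra, "CA")) >= 2
}

#' Segment a chain into contiguous altloc runs
#'
#' Maximal runs of sequence-adjacent altloc-harboring residues become
#' segments numbered `1, 2, ...` from the chain start. Adjacency requires
#' consecutive author numbering (insertion-code siblings count as adjacent),
#' so both unmodelled gaps and intervening single-conformer residues split a
#' run.
#'
#' @param chain A `chain_structure`.
#' @return Data frame with one row per segment: `seg_id`, `start`, `end`
#'   (author residue numbers, inclusive), `start_key`, `end_key`, `length`
#'   (number of residues spanned). Zero rows when no residue harbors an
#'   altloc.
#' @export
segment_chain <- function(chain) {
  stopifnot(inherits(chain, "chain_structure"))
  res <- chain$residues
  empty <- data.frame(seg_id = integer(), start = integer(), end = integer(),
                      start_key = character(), end_key = character(),
                      length = integer(), stringsAsFactors = FALSE)
  if (nrow(res) == 0) return(empty)
  harb <- vapply(res$key, function(k) harbors_altloc(chain, k), logical(1))
  segs <- list()
  run_start <- NA_integer_
  for (i in seq_len(nrow(res))) {
    if (harb[i]) {
      extends <- !is.na(run_start) && harb[i - 1] && seq_adjacent(res, i - 1, i)
      if (!extends) {
        if (!is.na(run_start)) segs[[length(segs) + 1]] <- c(run_start, run_end)
        run_start <- i
      }
      run_end <- i
    } else if (!is.na(run_start)) {
      segs[[length(segs) + 1]] <- c(run_start, run_end)
      run_start <- NA_integer_
    }
  }
  if (!is.na(run_start)) segs[[length(segs) + 1]] <- c(run_start, run_end)
  if (length(segs) == 0) return(empty)
  out <- do.call(rbind, lapply(seq_along(segs), function(s) {
    i0 <- segs[[s]][1]; i1 <- segs[[s]][2]
    data.frame(seg_id = s, start = res$author_seq_num[i0],
               end = res$author_seq_num[i1],
               start_key = res$key[i0], end_key = res$key[i1],
               length = i1 - i0 + 1L, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Map each residue to its segment id
#'
#' @param chain A `chain_structure`.
#' @param segments Output of [segment_chain()] (computed if omitted).
#' @return Named integer vector (residue key -> seg_id, `NA` outside
#'   segments).
#' @export
segment_ids <- function(chain, segments = NULL) {
  if (is.null(segments)) segments <- segment_chain(chain)
  res <- chain$residues
  out <- setNames(rep(NA_integer_, nrow(res)), res$key)
  for (s in seq_len(nrow(segments))) {
    i0 <- match(segments$start_key[s], res$key)
    i1 <- match(segments$end_key[s], res$key)
    out[res$key[i0:i1]] <- segments$seg_id[s]
  }
  out
}
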