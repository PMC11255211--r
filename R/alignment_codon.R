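#' @title Sequence alignment and codon assignment
#' @name alignment_codon
#' @description Global pairwise alignment of chain sequences to UniProt
#'   records (BLOSUM80, gap open -10, gap extend -0.5) to index residues, and
#'   codon assignment by aligning translated ENA coding sequences.
NULL

blosum80 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM80", package = "Biostrings", envir = e)
      m <<- e$BLOSUM80
    }
    m
  }
})

#' Global pairwise alignment of two amino-acid sequences
#'
#' Needleman-Wunsch-style global alignment under the BLOSUM80 substitution
#' matrix with affine gap penalties: a gap of length `k` costs
#' `10 + 0.5 * k`. Returns the residue-index correspondence of matched
#' columns; the mapping is strictly increasing over aligned positions.
#'
#' @param query Amino-acid string (uppercase one-letter codes, `X` allowed).
#' @param target Amino-acid string.
#' @return List with `index_map` (integer vector of length `nchar(query)`;
#'   element `i` holds the 0-based target index aligned to 0-based query
#'   index `i - 1`, or `NA` when unaligned) and `score`.
#' @export
align_pair <- function(query, target) {
  if (!nzchar(query) || !nzchar(target)) {
    stop("align_pair: sequences must be non-empty")
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target),
    substitutionMatrix = blosum80(), gapOpening = 10, gapExtension = 0.5,
    type = "global")
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  ta <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  index_map <- rep(NA_integer_, nchar(query))
  qi <- 0L; ti <- 0L
  for (k in seq_along(qa)) {
    qgap <- qa[k] == "-"; tgap <- ta[k] == "-"
    if (!qgap) qi <- qi + 1L
    if (!tgap) ti <- ti + 1L
    if (!qgap && !tgap) index_map[qi] <- ti - 1L
  }
  list(index_map = index_map, score = Biostrings::score(pa))
}

#' Translate a coding sequence with the standard genetic code
#'
#' The first stop codon terminates translation; a terminal stop is therefore
#' silently trimmed. Length must be divisible by three and only A/C/G/T
#' (case-insensitive) are accepted.
#'
#' @param nucleotides Nucleotide string.
#' @return Amino-acid string.
#' @export
translate_cds <- function(nucleotides) {
  nt <- toupper(nucleotides)
  if (nchar(nt) %% 3 != 0) {
    stop("translate_cds: sequence length not divisible by 3")
  }
  n <- nchar(nt) / 3
  starts <- 3 * (seq_len(n) - 1) + 1
  codons <- substring(nt, starts, starts + 2)
  bad <- grepl("[^ACGT]", codons)
  if (any(bad)) {
    stop("translate_cds: non-ACGT triplet '", codons[which(bad)[1]], "'")
  }
  aa <- Biostrings::GENETIC_CODE[codons]
  stop_at <- which(aa == "*")
  if (length(stop_at) > 0) aa <- aa[seq_len(stop_at[1] - 1)]
  paste(aa, collapse = "")
}

#' Assign codons to chain residues from a set of coding sequences
#'
#' Each coding sequence is translated and globally aligned to the chain
#' sequence (same scoring as [align_pair()]); the codon each contributes at
#' each aligned residue is collected. The assigned codon is the most common
#' (ties broken by lexicographic order) and the codon score is the proportion
#' of contributing sequences that carried it, with the denominator being the
#' number of coding sequences contributing any codon at that position.
#' Unalignable or untranslatable sequences contribute nothing.
#'
#' @param chain_seq Amino-acid string of the chain.
#' @param cds_set Character vector (possibly named) of nucleotide coding
#'   sequences; may be empty.
#' @return Data frame with one row per chain residue: `pos` (1-based),
#'   `codon` (3-letter string, `""` when unassigned), `codon_score`
#'   (in `[0, 1]`, 0 when unassigned), `codon_opts` ('/'-delimited sorted
#'   distinct codons observed).
#' @export
assign_codons <- function(chain_seq, cds_set = character()) {
  n <- nchar(chain_seq)
  tallies <- vector("list", n)
  for (cds in cds_set) {
    aa <- tryCatch(translate_cds(cds), error = function(e) NULL)
    if (is.null(aa) || !nzchar(aa)) next
    al <- tryCatch(align_pair(chain_seq, aa), error = function(e) NULL)
    if (is.null(al)) next
    for (i in seq_len(n)) {
      j <- al$index_map[i]          # 0-based index into translated sequence
      if (is.na(j)) next
      codon <- substr(cds, 3 * j + 1, 3 * j + 3)
      tallies[[i]] <- c(tallies[[i]], codon)
    }
  }
  codon <- character(n); score <- numeric(n); opts <- character(n)
  for (i in seq_len(n)) {
    tl <- tallies[[i]]
    if (is.null(tl)) { codon[i] <- ""; score[i] <- 0; opts[i] <- ""; next }
    tab <- table(tl)
    winners <- names(tab)[tab == max(tab)]
    codon[i] <- sort(winners, method = "radix")[1]
    score[i] <- as.numeric(max(tab)) / length(tl)
    opts[i] <- paste(sort(names(tab), method = "radix"), collapse = "/")
  }
  data.frame(pos = seq_len(n), codon = codon, codon_score = score,
             codon_opts = opts, stringsAsFactors = FALSE)
}

#' One-letter sequence of the modelled residues of a chain
#'
#' @param chain A `chain_structure`.
#' @return Amino-acid string over modelled residues in chain order.
#' @export
chain_sequence <- function(chain) {
  paste(chain$residues$one_letter, collapse = "")
}
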