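#' @title Non-redundant sequence clustering
#' @name clustering
#' @description Assigns chains to non-redundant clusters by amino-acid
#'   sequence (default minimum identity 0.5, bidirectional coverage 0.8).
#'   When an external clustering tool (mmseqs) is on the PATH it is used via
#'   its FASTA-in / TSV-out interface; otherwise a deterministic built-in
#'   greedy centroid algorithm with the identical output contract applies.
NULL

# identity and coverage of two sequences from a global alignment
pairwise_identity <- function(a, b) {
  al <- align_pair(a, b)
  aligned <- sum(!is.na(al$index_map))
  if (aligned == 0) return(list(identity = 0, cov_a = 0, cov_b = 0))
  matches <- sum(strsplit(a, "")[[1]][which(!is.na(al$index_map))] ==
                 strsplit(b, "")[[1]][al$index_map[!is.na(al$index_map)] + 1])
  # alignment length = columns spanned by the global alignment
  gaps_a <- nchar(b) - aligned; gaps_b <- nchar(a) - aligned
  alen <- aligned + gaps_a + gaps_b
  list(identity = matches / alen,
       cov_a = aligned / nchar(a), cov_b = aligned / nchar(b))
}

#' Cluster sequences into non-redundant families
#'
#' Built-in algorithm: sequences are visited longest-first (ties by
#' identifier, making the partition independent of input order); each
#' unassigned sequence seeds a new cluster and later sequences join it when
#' global-alignment identity is at least `min_id` and the aligned fraction of
#' both sequences is at least `cov` against the centroid. Cluster ids are
#' dense from 1 in centroid order.
#'
#' @param seqs Named character vector (identifier -> amino-acid sequence).
#' @param min_id Minimum sequence identity (default 0.5).
#' @param cov Minimum bidirectional coverage (default 0.8).
#' @param tool `"auto"` (external tool if on PATH, else built-in),
#'   `"builtin"`, or `"mmseqs"`.
#' @return List with `assignment` (named integer vector: identifier ->
#'   cluster id) and `params`.
#' @export
cluster_sequences <- function(seqs, min_id = 0.5, cov = 0.8,
                              tool = c("auto", "builtin", "mmseqs")) {
  tool <- match.arg(tool)
  stopifnot(length(seqs) > 0, !is.null(names(seqs)), all(nzchar(seqs)))
  if (tool %in% c("auto", "mmseqs") && nzchar(Sys.which("mmseqs"))) {
    res <- tryCatch(cluster_sequences_mmseqs(seqs, min_id, cov),
                    error = function(e) {
                      warning("external clustering tool failed (",
                              conditionMessage(e), "); using built-in ",
                              "greedy clustering")
                      NULL
                    })
    if (!is.null(res)) return(res)
  } else if (tool == "mmseqs") {
    warning("mmseqs not found on PATH; using built-in greedy clustering")
  }
  ord <- order(-nchar(seqs), names(seqs), method = "radix")
  ids <- names(seqs)[ord]
  assignment <- setNames(rep(NA_integer_, length(seqs)), names(seqs))
  centroids <- character(0)   # ids of cluster representatives
  for (id in ids) {
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      p <- pairwise_identity(seqs[[id]], seqs[[centroids[ci]]])
      if (p$identity >= min_id && p$cov_a >= cov && p$cov_b >= cov) {
        assignment[id] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, id)
      assignment[id] <- length(centroids)
    }
  }
  list(assignment = assignment,
       params = list(min_seq_id = min_id, coverage = cov, tool = "builtin"))
}

# external-tool path: FASTA in, cluster TSV out
cluster_sequences_mmseqs <- function(seqs, min_id, cov) {
  dir <- tempfile("mmseqs_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  fa <- file.path(dir, "in.fasta")
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), fa)
  out <- file.path(dir, "clu")
  status <- system2("mmseqs",
                    c("easy-cluster", fa, out, file.path(dir, "tmp"),
                      "--min-seq-id", min_id, "-c", cov, "--cov-mode", "0"),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("mmseqs exited with status ", status)
  tsv <- read.csv(paste0(out, "_cluster.tsv"), sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE)
  reps <- unique(tsv[[1]])
  cl <- setNames(match(tsv[[1]], reps), tsv[[2]])
  assignment <- setNames(cl[names(seqs)], names(seqs))
  list(assignment = assignment,
       params = list(min_seq_id = min_id, coverage = cov, tool = "mmseqs"))
}
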