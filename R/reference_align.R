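#' Optimal local alignment by affine-gap Smith-Waterman
#'
#' Three-state (Gotoh) dynamic programming over the full matrix pair, with
#' gap cost `open + extend * (L - 1)` for a gap of length L. One optimal
#' path is returned; traceback ties are broken deterministically in the
#' fixed order match > delete > insert, earliest coordinates first.
#'
#' @param a,b residue strings or single-row [protein_set()]s.
#' @param matrix substitution matrix or name.
#' @param gaps [gap_penalties()].
#' @return `NULL` when the optimum is 0 (empty alignment); otherwise a list
#'   with `score`, `blocks` (0-based `qstart`, `tstart`, `len`), and the
#'   half-open hull intervals `q_start`, `q_end`, `t_start`, `t_end`.
#' @export
smith_waterman <- function(a, b, matrix = "BLOSUM62", gaps = gap_penalties(11, 1)) {
  qa <- as_single_query(a)
  qb <- as_single_query(b)
  matrix <- builtin_matrix(matrix)
  S <- score_table(matrix)
  r <- cpp_sw(qa$codes, qb$codes, S, gaps$open, gaps$extend)
  if (r$score <= 0) return(NULL)
  bl <- r$blocks
  n <- nrow(bl)
  list(score = r$score, blocks = bl,
       q_start = unname(bl[1, 1]), q_end = unname(bl[n, 1] + bl[n, 3]),
       t_start = unname(bl[1, 2]), t_end = unname(bl[n, 2] + bl[n, 3]))
}

#' Rigorous all-vs-all search (Smith-Waterman baseline)
#'
#' Aligns every query against every library sequence with
#' [smith_waterman()], attaches E-values, and filters and sorts exactly as
#' [search()] does: one hit per (query, target) pair, E-value ascending.
#' When `queries` and `library` are the same collection, scores are
#' computed once per unordered pair and mirrored.
#'
#' @param queries,library [protein_set()]s.
#' @param matrix substitution matrix or name.
#' @param gaps [gap_penalties()].
#' @param gumbel [gumbel_params()]; calibrated deterministically when omitted.
#' @param freqs background composition used for on-the-fly calibration.
#' @param evalue_max maximal reported E-value.
#' @param score_min minimal reported score.
#' @return A `hit_table` data frame.
#' @export
sw_search <- function(queries, library, matrix = "BLOSUM62",
                      gaps = gap_penalties(11, 1), gumbel = NULL,
                      freqs = default_freqs(), evalue_max = 10, score_min = 0L) {
  if (is.character(queries)) queries <- read_fasta(queries)
  if (is.character(library)) library <- read_fasta(library)
  stopifnot(inherits(queries, "protein_set"), inherits(library, "protein_set"))
  matrix <- builtin_matrix(matrix)
  if (is.null(gumbel)) {
    gumbel <- calibrate_gapped(matrix, gaps, freqs,
                               n_pairs = 500L, seq_len = 100L, seed = 1L)
  }
  hits <- finish_hits(NULL, scheme_header(matrix$name, gaps, gumbel, Inf))
  if (nrow(library) == 0 || nrow(queries) == 0) return(hits)
  S <- score_table(matrix)
  qc <- encode_residues(queries$seq)
  symmetric <- identical(queries$id, library$id) &&
    identical(queries$seq, library$seq)
  tc <- if (symmetric) qc else encode_residues(library$seq)
  scores <- cpp_sw_scores(qc, tc, S, gaps$open, gaps$extend, symmetric)
  db_len <- sum(nchar(library$seq))
  qlen <- nchar(queries$seq)
  ev <- gumbel$K * outer(as.numeric(qlen), rep(as.numeric(db_len), nrow(library))) *
    exp(-gumbel$lambda * scores)
  keep <- which(scores >= pmax(score_min, 1L) & ev <= evalue_max, arr.ind = TRUE)
  if (nrow(keep) == 0) return(hits)
  # traceback once per needed pair; for symmetric searches reuse the
  # transposed path of the mirror pair
  path_cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(keep))
  for (k in seq_len(nrow(keep))) {
    i <- keep[k, 1]; j <- keep[k, 2]
    key <- if (symmetric) paste(min(i, j), max(i, j)) else paste(i, j)
    bl <- get0(key, envir = path_cache, inherits = FALSE)
    transposed <- FALSE
    if (is.null(bl)) {
      ii <- if (symmetric) min(i, j) else i
      jj <- if (symmetric) max(i, j) else j
      bl <- cpp_sw(qc[[ii]], tc[[jj]], S, gaps$open, gaps$extend)$blocks
      assign(key, bl, envir = path_cache)
    }
    if (symmetric && i > j) transposed <- TRUE
    if (transposed) bl <- bl[, c(2, 1, 3), drop = FALSE]
    rows[[k]] <- data.frame(query_id = queries$id[i], target_id = library$id[j],
                            score = scores[i, j], evalue = ev[i, j],
                            blocks = format_blocks(bl), stringsAsFactors = FALSE)
  }
  finish_hits(do.call(rbind, rows),
              scheme_header(matrix$name, gaps, gumbel, Inf))
}
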