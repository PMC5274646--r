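#' Build a suffix-array index over a protein library
#'
#' Sequences are concatenated with unique terminators and all residue
#' positions are sorted in lexicographic suffix order. The index is
#' independent of any scoring scheme; seeds are exact matches over the
#' canonical protein alphabet.
#'
#' @param library a [protein_set()] (or path to a FASTA file).
#' @return A `suffix_index` object.
#' @export
build_index <- function(library) {
  if (is.character(library) && length(library) == 1) library <- read_fasta(library)
  stopifnot(inherits(library, "protein_set"))
  if (nrow(library) == 0) stop("cannot index an empty library")
  codes <- encode_residues(library$seq)
  A <- length(RESIDUE_ALPHABET)
  n <- nrow(library)
  lens <- lengths(codes)
  # interleave sequences and unique terminator codes A, A+1, ...
  text <- integer(sum(lens) + n)
  seq_of <- integer(length(text))
  seq_start <- integer(n)
  at <- 1L
  for (i in seq_len(n)) {
    seq_start[i] <- at - 1L
    text[at:(at + lens[i] - 1L)] <- codes[[i]]
    seq_of[at:(at + lens[i] - 1L)] <- i - 1L
    text[at + lens[i]] <- A + i - 1L
    seq_of[at + lens[i]] <- -1L
    at <- at + lens[i] + 1L
  }
  sa <- cpp_build_sa(text, A)
  structure(list(library = library, text = text, sa = sa,
                 seq_of = seq_of, seq_start = seq_start, seq_len = lens,
                 n_residues = sum(lens)),
            class = "suffix_index")
}

#' @export
print.suffix_index <- function(x, ...) {
  cat("suffix_index:", nrow(x$library), "sequence(s),",
      x$n_residues, "residues\n")
  invisible(x)
}

#' Count occurrences of a pattern in an indexed library
#'
#' Binary search on the suffix array; matches never cross sequence
#' boundaries.
#'
#' @param index a [build_index()] result.
#' @param pattern non-empty residue string.
#' @return Integer occurrence count.
#' @export
count_occurrences <- function(index, pattern) {
  stopifnot(inherits(index, "suffix_index"), nzchar(pattern))
  p <- encode_residues(toupper(pattern))[[1]]
  if (anyNA(p)) return(0L)
  cpp_sa_count(index$text, index$sa, p)
}

#' Adaptive seeds of a query against an indexed library
#'
#' At each query position the seed is the shortest substring of length at
#' least `min_seed_len` whose library frequency is at most `m`; one seed is
#' emitted per library occurrence. Positions where the frequency never
#' drops to `m` within the query yield no seed.
#'
#' @param query a single-row [protein_set()] or residue string.
#' @param index a [build_index()] result.
#' @param m seed rareness limit (may be `Inf`).
#' @param min_seed_len minimal seed length.
#' @return Data frame with 0-based `query_pos`, 1-based `target_seq`,
#'   0-based `target_pos`, `length` and `freq`.
#' @export
adaptive_seeds <- function(query, index, m = 10, min_seed_len = 1L) {
  stopifnot(inherits(index, "suffix_index"), m >= 1)
  q <- as_single_query(query)
  sm <- cpp_adaptive_seeds(index$text, index$sa, q$codes,
                           as.numeric(m), as.integer(min_seed_len))
  tg <- index$seq_of[sm[, "tpos"] + 1L]
  data.frame(query_pos = sm[, "qpos"],
             target_seq = tg + 1L,
             target_pos = sm[, "tpos"] - index$seq_start[tg + 1L],
             length = sm[, "len"],
             freq = sm[, "freq"])
}

as_single_query <- function(query) {
  if (is.character(query)) query <- protein_set("query", query)
  stopifnot(inherits(query, "protein_set"), nrow(query) == 1)
  list(id = query$id, seq = query$seq, codes = encode_residues(query$seq)[[1]])
}

#' Search parameters for the adaptive-seed engine
#'
#' @param m seed rareness limit: seeds must occur at most `m` times in the
#'   library (default 10; `Inf` disables the limit).
#' @param min_seed_len minimal seed length in residues.
#' @param matrix substitution matrix or name ("BLOSUM62" bundled).
#' @param gaps [gap_penalties()]; defaults to 11/1, or 13/2 when the MIQS
#'   matrix is selected by name.
#' @param freqs background composition for E-value statistics.
#' @param gumbel optional [gumbel_params()]; calibrated on the fly
#'   (deterministically) when omitted.
#' @param gapless_xdrop score drop ending gapless extension.
#' @param gapped_xdrop score drop ending gapped extension (may be `Inf`).
#' @param gapless_min minimal gapless segment score that triggers gapped
#'   extension.
#' @param score_min minimal reported alignment score.
#' @param evalue_max maximal reported E-value.
#' @return A `search_params` object.
#' @export
search_params <- function(m = 10, min_seed_len = 1L,
                          matrix = "BLOSUM62", gaps = NULL,
                          freqs = default_freqs(), gumbel = NULL,
                          gapless_xdrop = NULL, gapped_xdrop = NULL,
                          gapless_min = 25L, score_min = 0L,
                          evalue_max = 10) {
  mat_name <- if (is.character(matrix)) matrix else matrix$name
  matrix <- builtin_matrix(matrix)
  if (is.null(gaps)) {
    gaps <- if (identical(mat_name, "MIQS")) gap_penalties(13, 2) else gap_penalties(11, 1)
  }
  if (m < 1) stop("m must be at least 1")
  if (is.null(gapless_xdrop)) gapless_xdrop <- 10 * max(matrix$scores)
  if (is.null(gapped_xdrop)) gapped_xdrop <- gaps$open + 30 * gaps$extend
  if (gapless_xdrop <= 0 || gapped_xdrop <= 0) stop("xdrop values must be positive")
  structure(list(m = m, min_seed_len = as.integer(min_seed_len),
                 matrix = matrix, gaps = gaps, freqs = freqs, gumbel = gumbel,
                 gapless_xdrop = gapless_xdrop, gapped_xdrop = gapped_xdrop,
                 gapless_min = as.integer(gapless_min),
                 score_min = as.integer(score_min), evalue_max = evalue_max),
            class = "search_params")
}

#' Gapless X-drop extension of a seed
#'
#' Widens a seed left and right, keeping the best running score and
#' stopping once the running score falls more than `xdrop` below the best.
#'
#' @param seed one row of [adaptive_seeds()] output (or a list with
#'   `query_pos`, `target_seq`, `target_pos`, `length`).
#' @param query the query (string or single-row [protein_set()]).
#' @param index the library index.
#' @param matrix substitution matrix or name.
#' @param xdrop nonnegative score drop limit.
#' @return List with 0-based half-open `q_start`, `q_end`, `t_start`,
#'   `t_end`, the `target_seq` index and the segment `score`.
#' @export
gapless_extend <- function(seed, query, index, matrix = "BLOSUM62", xdrop = 20) {
  q <- as_single_query(query)
  matrix <- builtin_matrix(matrix)
  S <- score_table(matrix)
  tg <- as.integer(seed$target_seq)
  tcodes <- target_codes(index, tg)
  r <- cpp_gapless_extend(q$codes, tcodes,
                          as.integer(seed$query_pos), as.integer(seed$target_pos),
                          as.integer(seed$length), S, as.numeric(xdrop))
  list(q_start = r[["qs"]], q_end = r[["qe"]],
       t_start = r[["ts"]], t_end = r[["te"]],
       target_seq = tg, score = r[["score"]])
}

#' Gapped X-drop extension around a gapless segment
#'
#' Runs affine-gap dynamic programming outward in both directions from the
#' segment's best-scoring column, pruning cells more than `xdrop` below the
#' running best.
#'
#' @param segment a [gapless_extend()] result (needs `q_end`, `t_end`,
#'   `target_seq` and a positive `score`).
#' @param query the query.
#' @param index the library index.
#' @param matrix substitution matrix or name.
#' @param gaps [gap_penalties()].
#' @param xdrop score drop limit (may be `Inf`).
#' @return List with `score`, block matrix `blocks` (0-based `qstart`,
#'   `tstart`, `len`) and the hull intervals.
#' @export
gapped_extend <- function(segment, query, index, matrix = "BLOSUM62",
                          gaps = gap_penalties(11, 1), xdrop = 41) {
  stopifnot(segment$score > 0)
  q <- as_single_query(query)
  matrix <- builtin_matrix(matrix)
  S <- score_table(matrix)
  tcodes <- target_codes(index, segment$target_seq)
  r <- cpp_gapped_extend(q$codes, tcodes,
                         as.integer(segment$q_end - 1L),
                         as.integer(segment$t_end - 1L),
                         S, gaps$open, gaps$extend, as.numeric(xdrop))
  b <- r$blocks
  list(score = r$score, blocks = b,
       q_start = unname(b[1, 1]), q_end = unname(b[nrow(b), 1] + b[nrow(b), 3]),
       t_start = unname(b[1, 2]), t_end = unname(b[nrow(b), 2] + b[nrow(b), 3]),
       target_seq = segment$target_seq)
}

target_codes <- function(index, tg) {
  s <- index$seq_start[tg] + 1L
  index$text[s:(s + index$seq_len[tg] - 1L)]
}

#' Adaptive-seed search of queries against an indexed library
#'
#' The pipeline per query: adaptive seeding, seed-independent gapless
#' segmentation of the seeded diagonals, gapped X-drop extension of
#' segments scoring at least `gapless_min` (skipping anchors covered by an
#' already-computed alignment of the same pair), E-value assignment, and
#' reporting of the single best alignment per (query, target) pair subject
#' to `score_min` and `evalue_max`. Hits are sorted by E-value ascending
#' with deterministic tie-breaking.
#'
#' @param queries a [protein_set()] of queries.
#' @param index a [build_index()] result.
#' @param params a [search_params()] object.
#' @return A `hit_table` data frame; see [write_hits()] for the columns.
#' @export
search <- function(queries, index, params = search_params()) {
  stopifnot(inherits(index, "suffix_index"), inherits(params, "search_params"))
  if (is.character(queries)) queries <- read_fasta(queries)
  gumbel <- params$gumbel
  if (is.null(gumbel)) {
    gumbel <- calibrate_gapped(params$matrix, params$gaps, params$freqs,
                               n_pairs = 500L, seq_len = 100L, seed = 1L)
  }
  S <- score_table(params$matrix)
  db_len <- index$n_residues
  rows <- vector("list", nrow(queries))
  qcodes <- encode_residues(queries$seq)
  for (qi in seq_len(nrow(queries))) {
    res <- cpp_search_query(qcodes[[qi]], index$text, index$sa,
                            index$seq_of, index$seq_start, index$seq_len, S,
                            as.numeric(params$m), params$min_seed_len,
                            params$gapless_min,
                            params$gaps$open, params$gaps$extend,
                            as.numeric(params$gapped_xdrop))
    if (length(res$target) == 0) next
    ev <- evalue(res$score, gumbel, nchar(queries$seq[qi]), db_len)
    keep <- res$score >= params$score_min & ev <= params$evalue_max
    if (!any(keep)) next
    idx <- which(keep)
    rows[[qi]] <- data.frame(
      query_id = queries$id[qi],
      target_id = index$library$id[res$target[idx] + 1L],
      score = res$score[idx],
      evalue = ev[idx],
      blocks = vapply(res$blocks[idx], format_blocks, character(1)),
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  finish_hits(hits, scheme_header(params$matrix$name, params$gaps, gumbel, params$m))
}

format_blocks <- function(b) {
  paste(sprintf("%d:%d:%d", b[, 1], b[, 2], b[, 3]), collapse = ",")
}

parse_blocks <- function(s) {
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  m <- matrix(as.integer(unlist(parts)), ncol = 3, byrow = TRUE,
              dimnames = list(NULL, c("qstart", "tstart", "len")))
  m
}

scheme_header <- function(name, gaps, gumbel, m) {
  sprintf("# seedaln matrix=%s open=%d extend=%d lambda=%.6g K=%.6g m=%s",
          name, gaps$open, gaps$extend, gumbel$lambda, gumbel$K,
          format(m, scientific = FALSE))
}

# attach intervals derived from blocks, order rows, set class
finish_hits <- function(hits, header = NULL) {
  if (is.null(hits) || nrow(hits) == 0) {
    hits <- data.frame(query_id = character(), target_id = character(),
                       score = integer(), evalue = numeric(),
                       q_start = integer(), q_end = integer(),
                       t_start = integer(), t_end = integer(),
                       blocks = character(), stringsAsFactors = FALSE)
  } else {
    bl <- lapply(hits$blocks, parse_blocks)
    hits$q_start <- vapply(bl, function(b) b[1, 1], integer(1))
    hits$q_end <- vapply(bl, function(b) b[nrow(b), 1] + b[nrow(b), 3], integer(1))
    hits$t_start <- vapply(bl, function(b) b[1, 2], integer(1))
    hits$t_end <- vapply(bl, function(b) b[nrow(b), 2] + b[nrow(b), 3], integer(1))
    hits <- hits[order(hits$evalue, -hits$score, hits$query_id, hits$target_id,
                       method = "radix"), ]
    hits <- hits[, c("query_id", "target_id", "score", "evalue",
                     "q_start", "q_end", "t_start", "t_end", "blocks")]
    rownames(hits) <- NULL
  }
  class(hits) <- c("hit_table", "data.frame")
  attr(hits, "scheme") <- header
  hits
}

#' @export
print.hit_table <- function(x, ...) {
  cat("hit_table with", nrow(x), "hit(s)\n")
  if (nrow(x) > 0) print.data.frame(head(as.data.frame(x)[, 1:8], 10))
  invisible(x)
}

#' Write a hit table as TSV
#'
#' One row per hit: query and target ids, integer score, E-value (6
#' significant digits), 0-based half-open intervals, and the alignment
#' blocks as comma-separated `qstart:tstart:len` triples. A `#` header
#' records the scoring scheme.
#'
#' @param hits a `hit_table`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_hits <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  header <- attr(hits, "scheme")
  if (!is.null(header)) writeLines(header, con)
  writeLines(paste(c("query_id", "target_id", "score", "evalue",
                     "q_start", "q_end", "t_start", "t_end", "blocks"),
                   collapse = "\t"), con)
  if (nrow(hits) > 0) {
    lines <- sprintf("%s\t%s\t%d\t%s\t%d\t%d\t%d\t%d\t%s",
                     hits$query_id, hits$target_id, hits$score,
                     sprintf("%.5e", hits$evalue),
                     hits$q_start, hits$q_end, hits$t_start, hits$t_end,
                     hits$blocks)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a hit table written by [write_hits()]
#'
#' Validates each row: blocks must be strictly increasing and
#' non-overlapping in both coordinates, and the intervals must be their
#' hull.
#'
#' @param path path to a hit TSV.
#' @return A `hit_table` data frame.
#' @export
read_hits <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) == 0) stop("hit file has no column header: ", path)
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!identical(cols[1:2], c("query_id", "target_id"))) {
    stop("unrecognised hit file header: ", path)
  }
  if (length(body) == 1) return(finish_hits(NULL))
  fields <- strsplit(body[-1], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9)) {
    stop("malformed hit row at line ", lineno[-1][which(nf != 9)[1]],
         ": expected 9 tab-separated fields")
  }
  m <- do.call(rbind, fields)
  hits <- data.frame(query_id = m[, 1], target_id = m[, 2],
                     score = as.integer(m[, 3]), evalue = as.numeric(m[, 4]),
                     q_start = as.integer(m[, 5]), q_end = as.integer(m[, 6]),
                     t_start = as.integer(m[, 7]), t_end = as.integer(m[, 8]),
                     blocks = m[, 9], stringsAsFactors = FALSE)
  for (i in seq_len(nrow(hits))) {
    b <- tryCatch(parse_blocks(hits$blocks[i]),
                  error = function(e) stop("malformed blocks at line ",
                                           lineno[-1][i], call. = FALSE))
    ok <- validate_blocks(b, hits$q_start[i], hits$q_end[i],
                          hits$t_start[i], hits$t_end[i])
    if (!isTRUE(ok)) stop("invalid hit at line ", lineno[-1][i], ": ", ok)
  }
  class(hits) <- c("hit_table", "data.frame")
  hits
}

# TRUE, or a string describing the violation
validate_blocks <- function(b, qs, qe, ts, te) {
  if (nrow(b) == 0) return("no blocks")
  if (any(b[, "len"] < 1)) return("empty block")
  if (nrow(b) > 1) {
    qend <- b[, "qstart"] + b[, "len"]
    tend <- b[, "tstart"] + b[, "len"]
    dq <- b[-1, "qstart"] - qend[-nrow(b)]
    dt <- b[-1, "tstart"] - tend[-nrow(b)]
    if (any(dq < 0) || any(dt < 0) || any(dq == 0 & dt == 0)) {
      return("blocks overlap or are not strictly increasing")
    }
  }
  hull_ok <- b[1, "qstart"] == qs && b[1, "tstart"] == ts &&
    b[nrow(b), "qstart"] + b[nrow(b), "len"] == qe &&
    b[nrow(b), "tstart"] + b[nrow(b), "len"] == te
  if (!hull_ok) return("intervals are not the hull of the blocks")
  TRUE
}

#' Recompute an alignment score from its blocks
#'
#' Sums matrix scores over block columns and subtracts affine gap costs
#' between blocks; used to check the score invariant of reported hits.
#'
#' @param hit one row of a `hit_table` (as a list or data frame row).
#' @param query_seq,target_seq residue strings.
#' @param matrix substitution matrix or name.
#' @param gaps [gap_penalties()].
#' @return Integer score.
#' @export
score_from_blocks <- function(hit, query_seq, target_seq,
                              matrix = "BLOSUM62", gaps = gap_penalties(11, 1)) {
  matrix <- builtin_matrix(matrix)
  S <- score_table(matrix)
  b <- parse_blocks(hit$blocks)
  q <- encode_residues(query_seq)[[1]]
  t <- encode_residues(target_seq)[[1]]
  total <- 0L
  for (k in seq_len(nrow(b))) {
    i <- b[k, "qstart"] + seq_len(b[k, "len"])
    j <- b[k, "tstart"] + seq_len(b[k, "len"])
    total <- total + sum(S[cbind(q[i] + 1L, t[j] + 1L)])
    if (k > 1) {
      gq <- b[k, "qstart"] - (b[k - 1, "qstart"] + b[k - 1, "len"])
      gt <- b[k, "tstart"] - (b[k - 1, "tstart"] + b[k - 1, "len"])
      for (g in c(gq, gt)) {
        if (g > 0) total <- total - (gaps$open + (g - 1L) * gaps$extend)
      }
    }
  }
  total
}
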