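test_that("suffix array orders all residue positions lexicographically", {
  idx <- build_index(protein_set("s1", "AB"))
  # two suffixes: "AB" then "B"
  expect_equal(idx$sa, c(0L, 1L))

  idx <- build_index(protein_set(c("x", "y"), c("BA", "AB")))
  expect_equal(sort(idx$sa), c(0L, 1L, 3L, 4L))  # permutation of residue positions

  expect_error(build_index(protein_set(character(), character())), "empty")
})

test_that("occurrence counts match naive scanning on random libraries", {
  withr::local_seed(7)
  # biased composition so short patterns repeat
  lib <- protein_set(paste0("s", 1:15), replicate(15, {
    random_protein(sample(30:90, 1), AA20[1:6])
  }))
  idx <- build_index(lib)
  for (k in 1:250) {
    pat <- random_protein(sample(1:4, 1), AA20[1:6])
    expect_identical(count_occurrences(idx, pat), naive_count(lib$seq, pat))
  }
  expect_identical(count_occurrences(idx, "WWWWW"), 0L)
  expect_identical(count_occurrences(build_index(protein_set("a", "AAAAA")), "A"), 5L)
})

test_that("adaptive seeds are minimal-length matches with frequency <= m", {
  withr::local_seed(8)
  lib <- protein_set(paste0("s", 1:10), replicate(10, random_protein(60, AA20[1:5])))
  idx <- build_index(lib)
  q <- lib$seq[1]
  for (m in c(1, 3, 10)) {
    seeds <- adaptive_seeds(q, idx, m = m)
    for (r in seq_len(nrow(seeds))) {
      s <- seeds[r, ]
      sub <- substr(q, s$query_pos + 1, s$query_pos + s$length)
      f <- naive_count(lib$seq, sub)
      expect_identical(f, s$freq)
      expect_lte(f, m)
      if (s$length > 1) {
        # the one-shorter prefix must still be too frequent
        pre <- substr(q, s$query_pos + 1, s$query_pos + s$length - 1)
        expect_gt(naive_count(lib$seq, pre), m)
      }
      # the seed occurrence matches exactly
      expect_identical(substr(lib$seq[s$target_seq], s$target_pos + 1,
                              s$target_pos + s$length), sub)
    }
    # one seed per occurrence of each selected seed string
    if (nrow(seeds) > 0) {
      per_pos <- table(seeds$query_pos)
      freq_pos <- vapply(split(seeds$freq, seeds$query_pos), unique, numeric(1))
      expect_equal(as.integer(per_pos), as.integer(freq_pos[names(per_pos)]))
    }
  }
})

test_that("the frequency bound is vacuous for huge m and strict for absent letters", {
  idx <- build_index(protein_set(c("a", "b"), c("ACDE", "ACDF")))
  seeds <- adaptive_seeds("ACD", idx, m = 1e6)
  # every query position's letter is present: a length-1 seed per occurrence
  expect_true(all(seeds$length == 1))
  expect_equal(nrow(seeds), 6)  # A, C, D each occur twice

  seeds <- adaptive_seeds("W", idx, m = 1e6)
  expect_equal(nrow(seeds), 0)

  # frequency never drops to <= m before the query end: no seed
  idx1 <- build_index(protein_set("a", "AAAA"))
  seeds <- adaptive_seeds("AA", idx1, m = 1)
  expect_equal(nrow(seeds), 0)
})

test_that("gapless extension follows the X-drop rule", {
  m <- builtin_matrix("BLOSUM62")
  idx <- build_index(protein_set("t", "MKVLATTRWQE"))
  # identical query: extension covers the full sequence, score = self-score
  seed <- list(query_pos = 4L, target_seq = 1L, target_pos = 4L, length = 2L)
  r <- gapless_extend(seed, "MKVLATTRWQE", idx, m, xdrop = 100)
  expect_equal(r$q_start, 0)
  expect_equal(r$q_end, 11)
  self <- sum(diag(m$scores)[match(strsplit("MKVLATTRWQE", "")[[1]],
                                   rownames(m$scores))])
  expect_equal(r$score, self)

  # a deep dip stops extension even with high-scoring residues beyond it
  # query:  WWWW C WWWW ; target: WWWW P WWWW  (W/W=+11, W/P=-4)
  idx2 <- build_index(protein_set("t", "WWWWPWWWW"))
  seed2 <- list(query_pos = 0L, target_seq = 1L, target_pos = 0L, length = 4L)
  r2 <- gapless_extend(seed2, "WWWWCWWWW", idx2, m, xdrop = 2)
  expect_equal(r2$q_end, 4)   # stops before the mismatch column
  expect_equal(r2$score, 44)
  # with a roomier budget it crosses the dip and takes the far residues
  r3 <- gapless_extend(seed2, "WWWWCWWWW", idx2, m, xdrop = 10)
  expect_equal(r3$q_end, 9)
  expect_equal(r3$score, 44 + m$scores["C", "P"] + 44)

  # xdrop = 0 stops at the first score drop
  r4 <- gapless_extend(seed2, "WWWWCWWWW", idx2, m, xdrop = 0)
  expect_equal(r4$q_end, 4)
})

test_that("gapped extension recovers whole alignments around an anchor", {
  m <- builtin_matrix("BLOSUM62")
  gp <- gap_penalties(11, 1)
  a <- "MKVLATTRWQEHFKLM"
  idx <- build_index(protein_set("t", a))
  seg <- list(q_end = 8L, t_end = 8L, target_seq = 1L, score = 10L)
  r <- gapped_extend(seg, a, idx, m, gp, xdrop = Inf)
  self <- sum(diag(m$scores)[match(strsplit(a, "")[[1]], rownames(m$scores))])
  expect_equal(r$score, self)
  expect_equal(nrow(r$blocks), 1)
  expect_equal(unname(r$blocks[1, "len"]), nchar(a))

  # one inserted residue: exactly one length-1 gap, score = matches - open
  b <- paste0(substr(a, 1, 8), "W", substr(a, 9, 16))
  idxb <- build_index(protein_set("t", b))
  rb <- gapped_extend(list(q_end = 4L, t_end = 4L, target_seq = 1L, score = 10L),
                      a, idxb, m, gp, xdrop = Inf)
  expect_equal(nrow(rb$blocks), 2)
  expect_equal(rb$score, self - gp$open)
  sw <- smith_waterman(a, b, m, gp)
  expect_equal(rb$score, sw$score)
})

test_that("gapped extension with unbounded X-drop matches the optimum through the anchor", {
  withr::local_seed(31)
  m <- builtin_matrix("BLOSUM62")
  gp <- gap_penalties(11, 1)
  for (k in 1:60) {
    anc <- random_protein(60)
    mem <- evolve_member(anc, 0.7, 0.05, default_freqs(), seed = k)
    sw <- smith_waterman(anc, mem$seq, m, gp)
    if (is.null(sw)) next
    idx <- build_index(protein_set("t", mem$seq))
    # anchor on the optimal path
    seg <- list(q_end = sw$blocks[1, 1] + 1L, t_end = sw$blocks[1, 2] + 1L,
                target_seq = 1L, score = 1L)
    r <- gapped_extend(seg, anc, idx, m, gp, xdrop = Inf)
    expect_equal(r$score, sw$score)
  }
})

test_that("hit tables round-trip through the TSV format", {
  withr::local_seed(12)
  bm <- small_benchmark()
  idx <- build_index(bm$library)
  gum <- gumbel_params(0.27, 0.05)
  p <- search_params(m = 10, gumbel = gum, evalue_max = 100)
  hits <- search(bm$library[1:12, ], idx, p)
  expect_gt(nrow(hits), 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits(hits, f)
  back <- read_hits(f)
  expect_equal(back$query_id, hits$query_id)
  expect_equal(back$target_id, hits$target_id)
  expect_identical(back$score, hits$score)
  expect_identical(back$blocks, hits$blocks)
  expect_equal(back$evalue, hits$evalue, tolerance = 1e-5)
  # writing what was read reproduces the file byte-for-byte (minus header)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_hits(back, f2)
  expect_identical(readLines(f2)[-1], readLines(f)[-(1:2)])

  # header-only file -> empty hit list
  writeLines(paste(c("query_id", "target_id", "score", "evalue", "q_start",
                     "q_end", "t_start", "t_end", "blocks"), collapse = "\t"), f)
  expect_equal(nrow(read_hits(f)), 0)

  # malformed rows are rejected with a line number
  writeLines(c("query_id\ttarget_id\tscore\tevalue\tq_start\tq_end\tt_start\tt_end\tblocks",
               "q\tt\t10\t1e-3\t0\t4"), f)
  expect_error(read_hits(f), "line 2")
  # overlapping blocks violate the invariant
  writeLines(c("query_id\ttarget_id\tscore\tevalue\tq_start\tq_end\tt_start\tt_end\tblocks",
               "q\tt\t10\t1.00000e-03\t0\t6\t0\t6\t0:0:4,2:2:4"), f)
  expect_error(read_hits(f), "line 2")
})

test_that("search reports the identical library sequence as the top hit", {
  bm <- small_benchmark()
  idx <- build_index(bm$library)
  gum <- gumbel_params(0.27, 0.05)
  q <- bm$library[3, ]
  class(q) <- class(bm$library)
  hits <- search(q, idx, search_params(gumbel = gum))
  expect_equal(hits$target_id[1], q$id)
  m <- builtin_matrix("BLOSUM62")
  self <- sum(diag(m$scores)[match(strsplit(q$seq, "")[[1]], rownames(m$scores))])
  expect_equal(hits$score[1], self)

  # empty query set -> empty hit table
  q0 <- bm$library[0, ]
  class(q0) <- class(bm$library)
  expect_equal(nrow(search(q0, idx, search_params(gumbel = gum))), 0)
})

test_that("search output is deterministic byte-for-byte", {
  bm <- small_benchmark()
  idx <- build_index(bm$library)
  gum <- gumbel_params(0.27, 0.05)
  p <- search_params(m = 10, gumbel = gum)
  qs <- bm$library[1:8, ]
  class(qs) <- class(bm$library)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_hits(search(qs, idx, p), f1)
  write_hits(search(qs, build_index(bm$library), p), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("reported hit scores are recomputable from their blocks", {
  bm <- small_benchmark()
  idx <- build_index(bm$library)
  gum <- gumbel_params(0.27, 0.05)
  gp <- gap_penalties(11, 1)
  qs <- bm$library[1:10, ]
  class(qs) <- class(bm$library)
  hits <- search(qs, idx, search_params(gumbel = gum, gaps = gp))
  seqs <- setNames(bm$library$seq, bm$library$id)
  for (i in seq_len(nrow(hits))) {
    expect_equal(score_from_blocks(hits[i, ], seqs[[hits$query_id[i]]],
                                   seqs[[hits$target_id[i]]], "BLOSUM62", gp),
                 hits$score[i])
  }
})
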