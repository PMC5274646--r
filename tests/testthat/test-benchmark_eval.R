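make_labels <- function() {
  homology_labels(
    id = c("q1", "q2", "q3", "t1", "t2", "t3", "t4"),
    fold = c("f1", "f1", "f2", "f1", "f1", "f2", "f3"),
    superfamily = c("sf1", "sf2", "sf3", "sf1", "sf2", "sf3", "sf4"))
}

test_that("hits are labelled SELF/TP/NEITHER/FP/EXCLUDED by classification", {
  lab <- make_labels()
  expect_equal(label_hit("q1", "t1", lab), "TP")        # same superfamily
  expect_equal(label_hit("q1", "t2", lab), "NEITHER")   # same fold, diff sf
  expect_equal(label_hit("q1", "t3", lab), "FP")        # different fold
  expect_equal(label_hit("q1", "q1", lab), "SELF")
  rules <- exclusion_rules("f1", "f2")
  expect_equal(label_hit("q1", "t3", lab, rules), "EXCLUDED")
  # superfamily-level exclusion tokens work too
  rules2 <- exclusion_rules("sf1", "sf4")
  expect_equal(label_hit("q1", "t4", lab, rules2), "EXCLUDED")
  expect_error(label_hit("q1", "nope", lab), "missing from labels")

  # rules only move hits between FP and EXCLUDED
  pairs <- expand.grid(q = lab$id, t = lab$id, stringsAsFactors = FALSE)
  l0 <- label_hit(pairs$q, pairs$t, lab)
  l1 <- label_hit(pairs$q, pairs$t, lab, rules)
  moved <- l0 != l1
  expect_true(all(l0[moved] == "FP" & l1[moved] == "EXCLUDED"))
})

test_that("query weights are 1/(other superfamily members), NA for singletons", {
  lab <- homology_labels(paste0("s", 1:7),
                         c("f1", "f1", "f1", "f1", "f2", "f2", "f3"),
                         c("sf1", "sf1", "sf1", "sf1", "sf2", "sf2", "sf3"))
  expect_equal(query_weight("s1", lab), 1 / 3)
  expect_equal(query_weight("s5", lab), 1)
  expect_true(is.na(query_weight("s7", lab)))
})

test_that("weighted ROC accumulates weights by distinct E-value", {
  # two queries (weights 1 and 1/3), each one TP then one FP
  lab <- homology_labels(
    id = c("a1", "a2", "b1", "b2", "b3", "b4", "x1", "x2"),
    fold = c("fa", "fa", "fb", "fb", "fb", "fb", "fx", "fy"),
    superfamily = c("sfa", "sfa", "sfb", "sfb", "sfb", "sfb", "sfx", "sfy"))
  hits <- finish_hits_for_test(data.frame(
    query_id = c("a1", "a1", "b1", "b1"),
    target_id = c("a2", "x1", "b2", "x2"),
    evalue = c(1e-5, 1e-2, 1e-4, 1e-1)))
  curve <- weighted_roc(hits, lab)
  expect_equal(nrow(curve), 4)
  expect_true(all(diff(curve$wtp) >= 0) && all(diff(curve$wfp) >= 0))
  expect_equal(curve$wtp[4], 4 / 3)
  expect_equal(curve$wfp[4], 4 / 3)
})

test_that("weighted ROC matches a from-scratch recount on random labelled hits", {
  withr::local_seed(33)
  n_sf <- 30
  ids <- paste0("p", 1:120)
  sf <- sample(paste0("sf", 1:n_sf), 120, replace = TRUE)
  fold <- paste0("f", match(sf, paste0("sf", 1:n_sf)) %% 12)
  lab <- homology_labels(ids, fold, sf)
  hits <- finish_hits_for_test(data.frame(
    query_id = sample(ids, 1000, replace = TRUE),
    target_id = sample(ids, 1000, replace = TRUE),
    evalue = signif(10^runif(1000, -8, 1), 3)))
  hits <- hits[!duplicated(paste(hits$query_id, hits$target_id)), ]
  curve <- weighted_roc(hits, lab)

  l <- label_hit(hits$query_id, hits$target_id, lab)
  w <- query_weight(hits$query_id, lab)
  keep <- l %in% c("TP", "FP") & !is.na(w)
  oracle <- recount_roc(hits$evalue[keep], l[keep], w[keep])
  expect_equal(curve$evalue, oracle$evalue)
  expect_equal(curve$wtp, oracle$wtp)
  expect_equal(curve$wfp, oracle$wfp)
})

test_that("wtp_at_fdr picks the best point under the FDR ceiling", {
  fp_free <- structure(data.frame(evalue = c(1e-3, 1e-2), wfp = c(0, 0),
                                  wtp = c(5, 10)),
                       class = c("roc_curve", "data.frame"))
  expect_equal(wtp_at_fdr(fp_free, 0.1), 10)

  curve <- structure(data.frame(evalue = c(1e-3, 1e-2), wfp = c(0, 2),
                                wtp = c(10, 10)),
                     class = c("roc_curve", "data.frame"))
  expect_equal(wtp_at_fdr(curve, 0.1), 10)  # second point has FDR 1/6 > 0.1

  empty <- structure(data.frame(evalue = numeric(), wfp = numeric(),
                                wtp = numeric()),
                     class = c("roc_curve", "data.frame"))
  expect_equal(wtp_at_fdr(empty, 0.1), 0)
})

test_that("roc_n implements the padding rule exactly", {
  expect_equal(roc_n(c(TRUE, TRUE, TRUE, TRUE, TRUE, rep(FALSE, 5)), 5), 1.0)
  # n FPs ahead of every TP: no TP is counted before any budgeted FP
  expect_equal(roc_n(c(rep(FALSE, 5), TRUE, TRUE), 5), 0.0)
  expect_equal(roc_n(c(FALSE, rep(TRUE, 4)), 1), 0.0)  # FP first, n = 1
  # T = 2, ranking TP, FP, TP, then nothing: (1+2+2+2+2)/(5*2)
  expect_equal(roc_n(c(TRUE, FALSE, TRUE), 5), 0.9)
  expect_equal(roc_n(logical(0), 5), 0)

  # against direct enumeration on random rankings
  withr::local_seed(44)
  for (k in 1:200) {
    v <- sample(c(TRUE, FALSE), sample(1:20, 1), replace = TRUE)
    n <- sample(1:8, 1)
    expect_equal(roc_n(v, n), recount_rocn(v, n))
  }

  # demoting an FP below a TP never decreases the score
  for (k in 1:50) {
    v <- sample(c(TRUE, FALSE), 12, replace = TRUE)
    i <- which(!v & c(v[-1], FALSE))  # FP immediately followed by TP
    if (length(i) == 0) next
    i <- i[1]
    v2 <- v
    v2[c(i, i + 1)] <- v[c(i + 1, i)]
    expect_gte(roc_n(v2, 5), roc_n(v, 5))
  }
})

test_that("mean ROC_n equals a per-query recount at the FDR cutoff", {
  withr::local_seed(55)
  ids <- paste0("p", 1:60)
  sf <- sample(paste0("sf", 1:12), 60, replace = TRUE)
  lab <- homology_labels(ids, paste0("f", match(sf, unique(sf)) %% 6), sf)
  hits <- finish_hits_for_test(data.frame(
    query_id = sample(ids, 600, replace = TRUE),
    target_id = sample(ids, 600, replace = TRUE),
    evalue = signif(10^runif(600, -6, 1), 3)))
  hits <- hits[!duplicated(paste(hits$query_id, hits$target_id)), ]
  got <- mean_rocn(hits, lab, n = 5, fdr_cutoff = 0.10)
  expect_gte(got, 0); expect_lte(got, 1)

  # recount: cutoff from the curve, then per-query enumeration
  curve <- weighted_roc(hits, lab)
  cutoff <- seedaln:::fdr_threshold(curve, 0.10)
  l <- label_hit(hits$query_id, hits$target_id, lab)
  w <- query_weight(hits$query_id, lab)
  keep <- l %in% c("TP", "FP") & !is.na(w) & hits$evalue <= cutoff
  d <- data.frame(q = hits$query_id[keep], e = hits$evalue[keep],
                  tp = l[keep] == "TP")
  eligible <- ids[!is.na(query_weight(ids, lab))]
  per_q <- vapply(eligible, function(qq) {
    h <- d[d$q == qq, ]
    h <- h[order(h$e, h$tp), ]  # FP first at ties
    recount_rocn(h$tp, 5)
  }, numeric(1))
  expect_equal(got, mean(per_q))

  # perfect rankings give mean 1: every query ranks all TPs first
  lab2 <- homology_labels(c("u1", "u2", "v1", "v2"),
                          c("fu", "fu", "fv", "fv"),
                          c("sfu", "sfu", "sfv", "sfv"))
  perfect <- finish_hits_for_test(data.frame(
    query_id = c("u1", "u1", "v1", "u2", "v2"),
    target_id = c("u2", "v1", "v2", "u1", "v1"),
    evalue = c(1e-6, 1e-2, 1e-5, 1e-6, 1e-6)))
  expect_equal(mean_rocn(perfect, lab2, n = 5, fdr_cutoff = 0.10), 1)
})

test_that("alignment pair extraction and quality follow the set definitions", {
  h <- list(blocks = "0:10:4")
  p <- alignment_pairs(h)
  expect_equal(p, cbind(qpos = 0:3, tpos = 10:13))

  h2 <- list(blocks = "0:10:3,5:14:2")
  p2 <- alignment_pairs(h2)
  expect_equal(nrow(p2), 5)
  expect_equal(anyDuplicated(paste(p2[, 1], p2[, 2])), 0)

  ref <- cbind(0:19, 0:19)
  expect_equal(unname(aln_quality(ref, ref)), c(1, 1))
  pred <- cbind(c(0:9, 100:129), c(0:9, 200:229))
  q <- aln_quality(pred, ref)
  expect_equal(unname(q), c(10 / 20, 10 / 40))
  # disjoint prediction
  expect_equal(unname(aln_quality(cbind(50, 60), ref)), c(0, 0))
  # empty prediction: precision 1 by convention
  expect_equal(unname(aln_quality(ref[0, , drop = FALSE], ref)), c(0, 1))
})

test_that("quality curve accumulates sensitivity and 1-precision by threshold", {
  refs <- data.frame(query_id = rep(c("a", "b"), each = 4),
                     target_id = rep(c("x", "y"), each = 4),
                     qpos = rep(0:3, 2), tpos = rep(0:3, 2))
  # prediction a-x exact; prediction b-y half right, half wrong + 2 extra
  hits <- finish_hits_for_test(data.frame(
    query_id = c("a", "b"), target_id = c("x", "y"),
    evalue = c(1e-4, 1e-2),
    blocks = c("0:0:4", "0:0:2,4:6:2")))
  curve <- quality_curve(hits, refs)
  expect_equal(curve$sum_sens, c(1, 1.5))
  expect_equal(curve$sum_one_minus_prec, c(0, 0.5))

  # missing reference -> error naming the pair
  hits2 <- finish_hits_for_test(data.frame(
    query_id = "zz", target_id = "x", evalue = 1e-3, blocks = "0:0:4"))
  expect_error(quality_curve(hits2, refs), "zz")

  # brute-force recount at every threshold
  withr::local_seed(66)
  n <- 40
  refs3 <- do.call(rbind, lapply(1:n, function(i) {
    data.frame(query_id = paste0("q", i), target_id = paste0("t", i),
               qpos = 0:9, tpos = 0:9)
  }))
  hits3 <- finish_hits_for_test(do.call(rbind, lapply(1:n, function(i) {
    st <- sample(0:6, 1)
    data.frame(query_id = paste0("q", i), target_id = paste0("t", i),
               evalue = signif(10^runif(1, -6, 0), 2),
               blocks = sprintf("%d:%d:%d", st, sample(0:6, 1), sample(2:8, 1)))
  })))
  curve3 <- quality_curve(hits3, refs3)
  sens <- prec <- numeric(n)
  for (i in seq_len(nrow(hits3))) {
    ref <- refs3[refs3$query_id == hits3$query_id[i], c("qpos", "tpos")]
    qq <- aln_quality(alignment_pairs(hits3[i, ]), as.matrix(ref))
    sens[i] <- qq[1]; prec[i] <- qq[2]
  }
  for (r in seq_len(nrow(curve3))) {
    inc <- hits3$evalue <= curve3$evalue[r]
    expect_equal(curve3$sum_sens[r], sum(sens[inc]))
    expect_equal(curve3$sum_one_minus_prec[r], sum(1 - prec[inc]))
  }
})
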