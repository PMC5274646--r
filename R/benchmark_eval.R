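#' Label a query-target hit against a homology classification
#'
#' A hit is `SELF` when query and target are the same sequence, `TP` when
#' they share a superfamily, `NEITHER` when they share a fold but not a
#' superfamily (such pairs may still be homologous and are kept out of both
#' counts), and otherwise `FP` — unless the pair's classifications appear
#' in the exclusion rules, which demotes it to `EXCLUDED`.
#'
#' @param query_id,target_id sequence ids present in `labels` (vectorised).
#' @param labels a [homology_labels()] table.
#' @param rules optional [exclusion_rules()].
#' @return Character vector of labels.
#' @export
label_hit <- function(query_id, target_id, labels, rules = NULL) {
  qi <- match(query_id, labels$id)
  ti <- match(target_id, labels$id)
  if (anyNA(qi) || anyNA(ti)) {
    bad <- unique(c(query_id[is.na(qi)], target_id[is.na(ti)]))
    stop("id(s) missing from labels: ", paste(head(bad, 5), collapse = ", "))
  }
  out <- rep("FP", length(qi))
  out[labels$fold[qi] == labels$fold[ti]] <- "NEITHER"
  out[labels$superfamily[qi] == labels$superfamily[ti]] <- "TP"
  out[query_id == target_id] <- "SELF"
  if (!is.null(rules) && length(rules$keys) > 0) {
    fp <- which(out == "FP")
    for (i in fp) {
      qtok <- c(labels$fold[qi[i]], labels$superfamily[qi[i]])
      ttok <- c(labels$fold[ti[i]], labels$superfamily[ti[i]])
      keys <- paste(pmin(rep(qtok, each = 2), ttok),
                    pmax(rep(qtok, each = 2), ttok), sep = "\t")
      if (any(keys %in% rules$keys)) out[i] <- "EXCLUDED"
    }
  }
  out
}

#' Per-query ROC weight
#'
#' 1 / (number of other library members of the query's superfamily); `NA`
#' when the query has no other member, in which case the query is dropped
#' from ROC analysis entirely.
#'
#' @param query_id sequence id(s) present in `labels`.
#' @param labels a [homology_labels()] table.
#' @param library_ids ids making up the searched library.
#' @return Numeric weight(s), `NA` for singleton-superfamily queries.
#' @export
query_weight <- function(query_id, labels, library_ids = labels$id) {
  qi <- match(query_id, labels$id)
  if (anyNA(qi)) {
    stop("id(s) missing from labels: ",
         paste(unique(query_id[is.na(qi)]), collapse = ", "))
  }
  lib <- labels[labels$id %in% library_ids, ]
  sf_size <- table(lib$superfamily)
  n_other <- as.integer(sf_size[labels$superfamily[qi]])
  n_other[is.na(n_other)] <- 0L
  in_lib <- query_id %in% library_ids
  n_other <- n_other - as.integer(in_lib)
  ifelse(n_other > 0, 1 / n_other, NA_real_)
}

# shared preprocessing for the detection statistics: label, weight, drop
labelled_hits <- function(hits, labels, rules = NULL, library_ids = labels$id) {
  known <- hits$query_id %in% labels$id & hits$target_id %in% labels$id
  n_drop <- sum(!known)
  if (n_drop > 0) {
    message(n_drop, " hit(s) outside the labels table ignored")
    hits <- hits[known, ]
  }
  if (nrow(hits) == 0) {
    return(data.frame(query_id = character(), evalue = numeric(),
                      label = character(), weight = numeric()))
  }
  lab <- label_hit(hits$query_id, hits$target_id, labels, rules)
  w <- query_weight(hits$query_id, labels, library_ids)
  keep <- lab %in% c("TP", "FP") & !is.na(w)
  data.frame(query_id = hits$query_id[keep], evalue = hits$evalue[keep],
             label = lab[keep], weight = w[keep], stringsAsFactors = FALSE)
}

#' Weighted ROC curve over E-value thresholds
#'
#' Hits are labelled, SELF/NEITHER/EXCLUDED hits and queries without
#' another superfamily member are dropped, and the remaining hits are
#' accumulated in E-value order into weighted TP and FP counts. Hits
#' sharing an E-value are accumulated together before a point is emitted.
#'
#' @param hits a `hit_table` (deduplicated to the best hit per pair, as
#'   [search()] and [sw_search()] report).
#' @param labels a [homology_labels()] table.
#' @param rules optional [exclusion_rules()].
#' @param library_ids ids of the searched library (defaults to all labelled
#'   ids).
#' @return A `roc_curve` data frame with columns `evalue`, `wfp`, `wtp`.
#' @export
weighted_roc <- function(hits, labels, rules = NULL, library_ids = labels$id) {
  d <- labelled_hits(hits, labels, rules, library_ids)
  d <- d[order(d$evalue), ]
  ev <- unique(d$evalue)
  wtp_step <- vapply(split(d$weight * (d$label == "TP"), match(d$evalue, ev)),
                     sum, numeric(1))
  wfp_step <- vapply(split(d$weight * (d$label == "FP"), match(d$evalue, ev)),
                     sum, numeric(1))
  out <- data.frame(evalue = ev,
                    wfp = cumsum(wfp_step[order(as.integer(names(wfp_step)))]),
                    wtp = cumsum(wtp_step[order(as.integer(names(wtp_step)))]))
  if (nrow(d) == 0) out <- data.frame(evalue = numeric(), wfp = numeric(),
                                      wtp = numeric())
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Weighted TP count at a false-discovery-rate ceiling
#'
#' The largest cumulative weighted TP count over ROC points whose weighted
#' FDR, wFP / (wFP + wTP), does not exceed `fdr`.
#'
#' @param curve a [weighted_roc()] result.
#' @param fdr FDR ceiling in (0, 1).
#' @return Numeric weighted TP count (0 when no point qualifies).
#' @export
wtp_at_fdr <- function(curve, fdr = 0.10) {
  stopifnot(fdr > 0, fdr < 1)
  if (nrow(curve) == 0) return(0)
  tot <- curve$wfp + curve$wtp
  ok <- tot > 0 & curve$wfp / tot <= fdr
  if (!any(ok)) return(0)
  max(curve$wtp[ok])
}

# E-value threshold at which wtp_at_fdr is achieved (-Inf when none)
fdr_threshold <- function(curve, fdr = 0.10) {
  if (nrow(curve) == 0) return(-Inf)
  tot <- curve$wfp + curve$wtp
  ok <- tot > 0 & curve$wfp / tot <= fdr
  if (!any(ok)) return(-Inf)
  best <- max(curve$wtp[ok])
  max(curve$evalue[ok & curve$wtp == best])
}

#' ROC_n score of one query's ranked hits
#'
#' ROC_n = (1 / (n T)) * sum_{i=1..n} t_i, where t_i is the number of TPs
#' ranked before the i-th FP and T is the query's TP count in the ranking.
#' When fewer than n FPs are observed, each missing FP contributes the
#' total observed TP count (unobserved hits are treated as FPs).
#'
#' @param is_tp logical vector: the query's TP/FP hits in E-value order
#'   (`TRUE` for TP). NEITHER/SELF/EXCLUDED hits must be removed upstream.
#' @param n FP budget (e.g. 5 for ROC_5).
#' @return Score in `[0, 1]`; 0 when the ranking holds no TP.
#' @export
roc_n <- function(is_tp, n = 5L) {
  T <- sum(is_tp)
  if (T == 0) return(0)
  tp_before <- cumsum(is_tp)[!is_tp]  # t_i for each observed FP
  ti <- c(head(tp_before, n), rep(T, max(0L, n - length(tp_before))))
  sum(ti) / (n * T)
}

#' Mean ROC_n over queries at an FDR-derived cutoff
#'
#' The global E-value cutoff is the threshold at which [wtp_at_fdr()] is
#' achieved on the weighted ROC curve; each eligible query (one with at
#' least one other superfamily member in the library) is scored by
#' [roc_n()] on its TP/FP hits within the cutoff, with ties in E-value
#' ranked pessimistically (FPs before TPs). Queries with no retrieved TP
#' score 0.
#'
#' @inheritParams weighted_roc
#' @param n FP budget per query.
#' @param fdr_cutoff FDR ceiling defining the cutoff.
#' @return Mean ROC_n over eligible queries (`NaN` when none is eligible).
#' @export
mean_rocn <- function(hits, labels, rules = NULL, n = 5L, fdr_cutoff = 0.10,
                      library_ids = labels$id) {
  curve <- weighted_roc(hits, labels, rules, library_ids)
  cutoff <- fdr_threshold(curve, fdr_cutoff)
  d <- labelled_hits(hits, labels, rules, library_ids)
  d <- d[d$evalue <= cutoff, ]
  w <- query_weight(labels$id, labels, library_ids)
  eligible <- labels$id[!is.na(w) & labels$id %in% library_ids]
  scores <- vapply(eligible, function(q) {
    h <- d[d$query_id == q, ]
    if (nrow(h) == 0) return(0)
    h <- h[order(h$evalue, h$label != "FP"), ]  # ties: FP first (pessimistic)
    roc_n(h$label == "TP", n)
  }, numeric(1))
  mean(scores)
}

#' Aligned residue pairs of a hit
#'
#' @param hit one row of a `hit_table`, or a list with a `blocks` field
#'   (string or 3-column matrix).
#' @return Integer matrix with columns `qpos`, `tpos` (0-based), one row
#'   per aligned column.
#' @export
alignment_pairs <- function(hit) {
  b <- hit$blocks
  if (is.character(b)) b <- parse_blocks(b)
  if (is.null(b) || nrow(b) == 0) {
    return(matrix(integer(), 0, 2, dimnames = list(NULL, c("qpos", "tpos"))))
  }
  q <- unlist(lapply(seq_len(nrow(b)),
                     function(k) b[k, 1] + seq_len(b[k, 3]) - 1L))
  t <- unlist(lapply(seq_len(nrow(b)),
                     function(k) b[k, 2] + seq_len(b[k, 3]) - 1L))
  cbind(qpos = q, tpos = t)
}

#' Alignment sensitivity and precision against a reference
#'
#' Sensitivity is |N intersect S| / |S| and precision |N intersect S| / |N|
#' for a predicted pair set N and reference pair set S. An empty prediction
#' has precision 1 (it contains no wrong pair) and sensitivity 0.
#'
#' @param pred,ref two-column matrices of (query, target) residue indices.
#' @return Named numeric vector `c(sensitivity, precision)`.
#' @export
aln_quality <- function(pred, ref) {
  stopifnot(nrow(ref) > 0)
  pk <- paste(pred[, 1], pred[, 2])
  rk <- paste(ref[, 1], ref[, 2])
  inter <- sum(pk %in% rk)
  c(sensitivity = inter / length(rk),
    precision = if (length(pk) == 0) 1 else inter / length(pk))
}

#' Alignment-quality curve over E-value thresholds
#'
#' Sweeps thresholds over the distinct hit E-values in ascending order; at
#' each threshold the pairs whose best hit has E-value at or below it
#' contribute their alignment sensitivity and (1 - precision) to the
#' cumulative sums.
#'
#' @param hits a `hit_table` with one best hit per evaluated pair.
#' @param refs reference alignments: data frame with columns `query_id`,
#'   `target_id`, `qpos`, `tpos` (as from [read_ref_pairs()]); either
#'   orientation of a pair may be given.
#' @return A `quality_curve` data frame with columns `evalue`, `sum_sens`,
#'   `sum_one_minus_prec`.
#' @export
quality_curve <- function(hits, refs) {
  key <- paste(refs$query_id, refs$target_id)
  tkey <- paste(refs$target_id, refs$query_id)
  sens <- numeric(nrow(hits))
  prec <- numeric(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    hk <- paste(hits$query_id[i], hits$target_id[i])
    if (any(key == hk)) {
      r <- refs[key == hk, c("qpos", "tpos")]
    } else if (any(tkey == hk)) {
      r <- refs[tkey == hk, c("tpos", "qpos")]
    } else {
      stop("no reference alignment for pair (", hits$query_id[i], ", ",
           hits$target_id[i], ")")
    }
    q <- aln_quality(alignment_pairs(hits[i, ]), as.matrix(r))
    sens[i] <- q["sensitivity"]
    prec[i] <- q["precision"]
  }
  ord <- order(hits$evalue)
  ev <- unique(hits$evalue[ord])
  grp <- match(hits$evalue[ord], ev)
  out <- data.frame(
    evalue = ev,
    sum_sens = cumsum(vapply(split(sens[ord], grp), sum, numeric(1))),
    sum_one_minus_prec = cumsum(vapply(split(1 - prec[ord], grp), sum, numeric(1))))
  if (nrow(hits) == 0) out <- data.frame(evalue = numeric(), sum_sens = numeric(),
                                         sum_one_minus_prec = numeric())
  class(out) <- c("quality_curve", "data.frame")
  out
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$wfp, x$wtp, type = "s", xlab = "weighted FP", ylab = "weighted TP", ...)
  invisible(x)
}

#' @export
plot.quality_curve <- function(x, ...) {
  plot(x$sum_one_minus_prec, x$sum_sens, type = "s",
       xlab = expression(sum(1 - precision)), ylab = "sum of sensitivity", ...)
  invisible(x)
}
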