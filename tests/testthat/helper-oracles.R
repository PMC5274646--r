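# Independent oracles, coded directly from the definitions and kept separate
# from the package's C++ implementations.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# brute-force affine-gap local alignment score, straight from the
# three-state recurrence
brute_sw_score <- function(a, b, S, open, extend) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  la <- length(a); lb <- length(b)
  H <- matrix(0, la + 1, lb + 1)
  E <- matrix(-Inf, la + 1, lb + 1)
  F <- matrix(-Inf, la + 1, lb + 1)
  best <- 0
  for (i in seq_len(la) + 1) {
    for (j in seq_len(lb) + 1) {
      E[i, j] <- max(H[i, j - 1] - open, E[i, j - 1] - extend)
      F[i, j] <- max(H[i - 1, j] - open, F[i - 1, j] - extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + S[a[i - 1], b[j - 1]], E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# overlapping substring count by direct scanning
naive_count <- function(seqs, pat) {
  L <- nchar(pat)
  sum(vapply(seqs, function(s) {
    n <- nchar(s)
    if (L > n) return(0L)
    sum(vapply(seq_len(n - L + 1), function(i) {
      substr(s, i, i + L - 1) == pat
    }, logical(1)))
  }, integer(1)))
}

random_protein <- function(len, letters = AA20) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# +1/-1 match/mismatch toy matrix over the 20 standard letters
toy_pm1 <- function() {
  sc <- matrix(-1L, 20, 20, dimnames = list(AA20, AA20))
  diag(sc) <- 1L
  structure(list(name = "pm1", alphabet = AA20, scores = sc),
            class = "substitution_matrix")
}

# from-scratch weighted ROC recount: at each distinct E-value threshold,
# recount weighted TPs and FPs among all hits at or below it
recount_roc <- function(ev, label, weight) {
  ths <- sort(unique(ev))
  data.frame(
    evalue = ths,
    wfp = vapply(ths, function(e) sum(weight[ev <= e & label == "FP"]), numeric(1)),
    wtp = vapply(ths, function(e) sum(weight[ev <= e & label == "TP"]), numeric(1)))
}

# roc_n by direct enumeration of the definition, including FP padding
recount_rocn <- function(is_tp, n) {
  T <- sum(is_tp)
  if (T == 0) return(0)
  fp_pos <- which(!is_tp)
  ti <- numeric(0)
  for (i in seq_len(n)) {
    if (i <= length(fp_pos)) {
      ti <- c(ti, sum(is_tp[seq_len(fp_pos[i] - 1)]))
    } else {
      ti <- c(ti, T)
    }
  }
  sum(ti) / (n * T)
}

# small shared synthetic benchmark (built once per test run)
small_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      specs <- do.call(rbind, lapply(1:10, function(f) {
        family_spec(3, 150, 0.40 + 0.02 * f, 0.02,
                    paste0("f", f), paste0("sf", f))
      }))
      cache <<- make_benchmark(specs, n_decoys = 50,
                               freqs = default_freqs(), seed = 101)
    }
    cache
  }
})

hit_key <- function(h) paste(h$query_id, h$target_id)

# build a minimal hit_table from the columns a test cares about
finish_hits_for_test <- function(d) {
  if (is.null(d$blocks)) d$blocks <- "0:0:1"
  if (is.null(d$score)) d$score <- 10L
  seedaln:::finish_hits(d)
}
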