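#' Family specification for the synthetic benchmark
#'
#' @param n_members number of sequences in the family.
#' @param ancestor_len ancestor length in residues.
#' @param target_identity expected pairwise identity (over matched columns)
#'   between family members, in (0, 1].
#' @param indel_rate indel events per site along each branch.
#' @param fold_id,superfamily_id classification tokens.
#' @return A one-row `family_spec` data frame; combine specs with `rbind`.
#' @export
family_spec <- function(n_members, ancestor_len, target_identity,
                        indel_rate = 0.02, fold_id, superfamily_id) {
  stopifnot(n_members >= 1, ancestor_len >= 1,
            target_identity > 0, target_identity <= 1, indel_rate >= 0)
  d <- data.frame(n_members = as.integer(n_members),
                  ancestor_len = as.integer(ancestor_len),
                  target_identity = target_identity,
                  indel_rate = indel_rate,
                  fold_id = as.character(fold_id),
                  superfamily_id = as.character(superfamily_id),
                  stringsAsFactors = FALSE)
  class(d) <- c("family_spec", "data.frame")
  d
}

#' Sample background (decoy) sequences
#'
#' @param n number of sequences.
#' @param len length in residues, a scalar or vector recycled over sequences.
#' @param freqs [background_freqs()] composition.
#' @param seed RNG seed.
#' @param prefix id prefix.
#' @return A [protein_set()] of i.i.d. sequences.
#' @export
sample_background <- function(n, len, freqs = default_freqs(), seed = 1L,
                              prefix = "bg") {
  if (n == 0) return(protein_set(character(), character()))
  len <- rep_len(as.integer(len), n)
  letters <- names(freqs)
  seqs <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      paste(sample(letters, len[i], replace = TRUE, prob = freqs), collapse = "")
    }, character(1))
  })
  protein_set(paste0(prefix, seq_len(n)), seqs)
}

#' Evolve one family member from an ancestor
#'
#' Matched columns are substituted at rate `1 - target_identity`, with the
#' replacement drawn from the background excluding the original residue, so
#' expected identity over matched columns equals `target_identity` exactly.
#' Indel events occur at `indel_rate` per site (insertions and deletions
#' equally likely) with geometric lengths of mean 2; inserted residues are
#' drawn from the background. The surviving (ancestor index, member index)
#' residue pairs are returned as ground truth.
#'
#' @param ancestor residue string.
#' @param target_identity expected identity to the ancestor over matched
#'   columns, in (0, 1].
#' @param indel_rate indel events per site.
#' @param freqs [background_freqs()].
#' @param seed RNG seed.
#' @return List with `seq` (the member's residues) and `pairs`, an integer
#'   matrix of 0-based (`anc`, `mem`) aligned positions.
#' @export
evolve_member <- function(ancestor, target_identity, indel_rate = 0.02,
                          freqs = default_freqs(), seed = 1L) {
  stopifnot(target_identity > 0, target_identity <= 1, indel_rate >= 0)
  letters <- names(freqs)
  anc <- strsplit(ancestor, "")[[1]]
  n <- length(anc)
  with_seed(seed, {
    # substitutions on every surviving column
    sub_mask <- runif(n) < (1 - target_identity)
    res <- anc
    if (any(sub_mask)) {
      for (i in which(sub_mask)) {
        p <- as.numeric(freqs)
        p[letters == anc[i]] <- 0
        res[i] <- sample(letters, 1, prob = p)
      }
    }
    # indel events: per ancestor site, deletion or insertion-before, each
    # at rate indel_rate / 2, geometric length with mean 2
    out <- character(0)
    anc_of <- integer(0)  # 0-based ancestor index per member residue, NA for inserts
    i <- 1L
    while (i <= n) {
      ev <- runif(1)
      if (ev < indel_rate / 2) {            # deletion starting here
        gap <- rgeom(1, 0.5) + 1L
        i <- i + gap
      } else if (ev < indel_rate) {         # insertion before this site
        ins <- rgeom(1, 0.5) + 1L
        out <- c(out, sample(letters, ins, replace = TRUE, prob = freqs))
        anc_of <- c(anc_of, rep(NA_integer_, ins))
        out <- c(out, res[i]); anc_of <- c(anc_of, i - 1L)
        i <- i + 1L
      } else {
        out <- c(out, res[i]); anc_of <- c(anc_of, i - 1L)
        i <- i + 1L
      }
    }
    keep <- !is.na(anc_of)
    list(seq = paste(out, collapse = ""),
         pairs = cbind(anc = anc_of[keep], mem = which(keep) - 1L))
  })
}

#' Generate a synthetic remote-homology benchmark
#'
#' For each family an ancestor is drawn from the background composition and
#' members are evolved independently from it; the per-branch identity is
#' chosen so that the expected pairwise identity between members equals the
#' family's `target_identity` (two independent branches at identity b give
#' pairwise identity b^2 plus a small chance-coincidence term). True
#' residue-pair alignments between members are composed through the
#' ancestor: positions surviving in both members and aligned to the same
#' ancestor column. Decoys carry singleton fold/superfamily labels.
#'
#' @param family_specs a `family_spec` data frame (rbind of [family_spec()]
#'   rows).
#' @param n_decoys number of background decoy sequences.
#' @param freqs [background_freqs()].
#' @param seed RNG seed; all per-family streams derive from it.
#' @return A `synthetic_benchmark`: list with `library` ([protein_set()]),
#'   `labels` ([homology_labels()]), `true_pairs` (data frame `query_id`,
#'   `target_id`, `qpos`, `tpos` for every unordered intra-family pair),
#'   `member_identity` (realised matched-column identity per pair), and
#'   `provenance`.
#' @export
make_benchmark <- function(family_specs, n_decoys = 0L,
                           freqs = default_freqs(), seed = 1L) {
  stopifnot(nrow(family_specs) >= 1)
  nf <- nrow(family_specs)
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, nf + 1L))
  letters <- names(freqs)
  cbar <- collision_prob(freqs)
  lib_id <- character(0); lib_seq <- character(0)
  lab_id <- character(0); lab_fold <- character(0); lab_sf <- character(0)
  tp <- vector("list", 0)
  ident <- vector("list", 0)
  for (f in seq_len(nf)) {
    spec <- family_specs[f, ]
    t_pair <- spec$target_identity
    if (t_pair < cbar) {
      stop("target_identity ", t_pair, " is below the chance level ",
           signif(cbar, 3))
    }
    # expected pairwise identity of two branches at identity b is
    # b^2 + (1-b)^2 * cbar; solve the quadratic for b
    b <- (cbar + sqrt(cbar^2 - (1 + cbar) * (cbar - t_pair))) / (1 + cbar)
    fam <- with_seed(sub_seeds[f], {
      anc <- paste(sample(letters, spec$ancestor_len, replace = TRUE,
                          prob = freqs), collapse = "")
      mseeds <- sample.int(.Machine$integer.max - 1L, spec$n_members)
      members <- lapply(seq_len(spec$n_members), function(k) {
        evolve_member(anc, b, spec$indel_rate, freqs, seed = mseeds[k])
      })
      members
    })
    ids <- sprintf("fam%d_m%d", f, seq_len(spec$n_members))
    lib_id <- c(lib_id, ids)
    lib_seq <- c(lib_seq, vapply(fam, `[[`, character(1), "seq"))
    lab_id <- c(lab_id, ids)
    lab_fold <- c(lab_fold, rep(spec$fold_id, spec$n_members))
    lab_sf <- c(lab_sf, rep(spec$superfamily_id, spec$n_members))
    if (spec$n_members >= 2) {
      for (i in seq_len(spec$n_members - 1)) {
        for (j in (i + 1):spec$n_members) {
          comp <- compose_pairs(fam[[i]]$pairs, fam[[j]]$pairs)
          if (nrow(comp) > 0) {
            tp[[length(tp) + 1]] <- data.frame(
              query_id = ids[i], target_id = ids[j],
              qpos = comp[, 1], tpos = comp[, 2], stringsAsFactors = FALSE)
            si <- strsplit(lib_seq[match(ids[i], lib_id)], "")[[1]]
            sj <- strsplit(lib_seq[match(ids[j], lib_id)], "")[[1]]
            ident[[length(ident) + 1]] <- data.frame(
              query_id = ids[i], target_id = ids[j],
              identity = mean(si[comp[, 1] + 1] == sj[comp[, 2] + 1]),
              n_cols = nrow(comp), stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (n_decoys > 0) {
    dlen <- with_seed(sub_seeds[nf + 1L], {
      round(sample(family_specs$ancestor_len, n_decoys, replace = TRUE) *
              runif(n_decoys, 0.9, 1.1))
    })
    dec <- sample_background(n_decoys, dlen, freqs,
                             seed = sub_seeds[nf + 1L], prefix = "decoy")
    lib_id <- c(lib_id, dec$id)
    lib_seq <- c(lib_seq, dec$seq)
    lab_id <- c(lab_id, dec$id)
    lab_fold <- c(lab_fold, paste0("dfold_", dec$id))
    lab_sf <- c(lab_sf, paste0("dsf_", dec$id))
  }
  structure(list(
    library = protein_set(lib_id, lib_seq),
    labels = homology_labels(lab_id, lab_fold, lab_sf),
    true_pairs = if (length(tp)) do.call(rbind, tp) else
      data.frame(query_id = character(), target_id = character(),
                 qpos = integer(), tpos = integer()),
    member_identity = if (length(ident)) do.call(rbind, ident) else
      data.frame(query_id = character(), target_id = character(),
                 identity = numeric(), n_cols = integer()),
    provenance = list(seed = seed, family_specs = family_specs,
                      n_decoys = n_decoys)),
    class = "synthetic_benchmark")
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat("synthetic_benchmark:", nrow(x$provenance$family_specs), "families,",
      nrow(x$library), "sequences,", nrow(x$true_pairs), "true residue pairs\n")
  invisible(x)
}

# probability that two independent substitutions of the same ancestor
# residue coincide, averaged over the ancestor composition
collision_prob <- function(freqs) {
  p <- as.numeric(freqs)
  sum(vapply(seq_along(p), function(a) {
    q <- p; q[a] <- 0; q <- q / sum(q)
    p[a] * sum(q^2)
  }, numeric(1)))
}

# compose two (ancestor, member) maps through shared ancestor columns
compose_pairs <- function(pi, pj) {
  k <- match(pi[, "anc"], pj[, "anc"])
  ok <- !is.na(k)
  cbind(qpos = pi[ok, "mem"], tpos = pj[k[ok], "mem"])
}
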