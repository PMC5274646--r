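#' Parse a substitution matrix in NCBI score-matrix format
#'
#' The format is `#`-prefixed comments, a header row of column letters,
#' then one labelled row of integer scores per letter. The parsed table
#' must be symmetric.
#'
#' @param text character scalar (file content) or character vector of lines.
#' @param name token naming the matrix.
#' @return A `substitution_matrix`: list with `name`, `alphabet` and the
#'   integer score table `scores`.
#' @export
parse_matrix <- function(text, name = "custom") {
  lines <- if (length(text) == 1 && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else as.character(text)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) < 2) stop("matrix text has no score rows")
  header <- strsplit(trimws(lines[keep[1]]), "\\s+")[[1]]
  n <- length(header)
  if (any(nchar(header) != 1)) stop("matrix header must be single letters")
  rows <- keep[-1]
  if (length(rows) < n) {
    missing <- setdiff(header, sub("\\s.*", "", trimws(lines[rows])))
    stop("missing matrix row(s) for: ", paste(missing, collapse = ", "))
  }
  scores <- matrix(NA_integer_, n, n, dimnames = list(header, header))
  for (ln in rows) {
    fields <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(fields) != n + 1) {
      stop("line ", ln, ": expected a row letter and ", n, " scores, got ",
           length(fields), " fields")
    }
    letter <- fields[1]
    if (!letter %in% header) stop("line ", ln, ": unknown row letter '", letter, "'")
    vals <- suppressWarnings(as.numeric(fields[-1]))
    if (any(is.na(vals)) || any(vals != round(vals))) {
      stop("line ", ln, ": non-integer score cell")
    }
    scores[letter, ] <- as.integer(vals)
  }
  if (anyNA(scores)) {
    stop("missing matrix row(s) for: ",
         paste(header[apply(scores, 1, anyNA)], collapse = ", "))
  }
  asym <- which(scores != t(scores), arr.ind = TRUE)
  if (nrow(asym) > 0) {
    stop("asymmetric matrix: score(", header[asym[1, 1]], ",",
         header[asym[1, 2]], ") != score(", header[asym[1, 2]], ",",
         header[asym[1, 1]], ")")
  }
  structure(list(name = name, alphabet = header, scores = scores),
            class = "substitution_matrix")
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat("substitution_matrix '", x$name, "': ", length(x$alphabet),
      " letters\n", sep = "")
  invisible(x)
}

#' Read a substitution matrix from a file
#' @param path path to an NCBI-format matrix file.
#' @param name token naming the matrix (defaults to the file name).
#' @return A `substitution_matrix`.
#' @export
read_matrix <- function(path, name = basename(path)) {
  parse_matrix(readLines(path), name = name)
}

.matrix_registry <- new.env(parent = emptyenv())

#' Look up a built-in or registered substitution matrix
#'
#' BLOSUM62 is bundled. Other matrices (e.g. MIQS, whose published values
#' are distributed with its original description) can be made available by
#' name with [register_matrix()].
#'
#' @param name matrix name token.
#' @return A `substitution_matrix`.
#' @export
builtin_matrix <- function(name) {
  if (inherits(name, "substitution_matrix")) return(name)
  if (identical(name, "BLOSUM62")) {
    if (is.null(.matrix_registry$BLOSUM62)) {
      .matrix_registry$BLOSUM62 <- read_matrix(
        system.file("extdata", "BLOSUM62", package = "seedaln"),
        name = "BLOSUM62")
    }
    return(.matrix_registry$BLOSUM62)
  }
  m <- get0(name, envir = .matrix_registry, inherits = FALSE)
  if (is.null(m)) {
    stop("unknown matrix '", name, "'; available: ",
         paste(sort(unique(c("BLOSUM62", ls(.matrix_registry)))), collapse = ", "))
  }
  m
}

#' Register a substitution matrix file under a name
#' @param name token to register (e.g. "MIQS").
#' @param path path to the NCBI-format matrix file.
#' @return The parsed `substitution_matrix`, invisibly.
#' @export
register_matrix <- function(name, path) {
  m <- read_matrix(path, name = name)
  assign(name, m, envir = .matrix_registry)
  invisible(m)
}

#' Affine gap penalties
#'
#' Costs are stored as positive magnitudes and subtracted during alignment;
#' a gap of length L costs `open + extend * (L - 1)`, i.e. the first gapped
#' residue is charged `open`.
#'
#' @param open nonnegative integer cost of the first gapped residue.
#' @param extend nonnegative integer cost per additional gapped residue.
#' @return A `gap_penalties` object.
#' @export
gap_penalties <- function(open, extend) {
  open <- as.integer(open); extend <- as.integer(extend)
  if (is.na(open) || is.na(extend) || extend < 1 || open < extend) {
    stop("gap penalties must satisfy open >= extend >= 1")
  }
  structure(list(open = open, extend = extend), class = "gap_penalties")
}

#' Background amino-acid frequencies
#'
#' @param p named numeric vector of letter probabilities (all positive,
#'   summing to 1 within 1e-6; renormalised exactly on construction).
#' @return A `background_freqs` named numeric vector.
#' @export
background_freqs <- function(p) {
  if (is.null(names(p)) || any(!nzchar(names(p)))) {
    stop("frequencies must be a named vector of letters")
  }
  if (any(p <= 0)) stop("all background frequencies must be positive")
  if (abs(sum(p) - 1) > 1e-6) stop("background frequencies must sum to 1")
  p <- p / sum(p)
  structure(p, class = "background_freqs")
}

#' Read background frequencies from a letter/probability TSV
#' @param path two-column tab-separated file: letter, probability.
#' @return A [background_freqs()] vector.
#' @export
read_freqs <- function(path) {
  d <- read.delim(path, header = FALSE, comment.char = "#",
                  col.names = c("letter", "p"),
                  colClasses = c("character", "numeric"))
  background_freqs(setNames(d$p, d$letter))
}

#' Default background composition (Robinson-Robinson)
#' @return A [background_freqs()] vector over the 20 standard letters.
#' @export
default_freqs <- function() {
  read_freqs(system.file("extdata", "robinson_freqs.tsv", package = "seedaln"))
}

#' Uniform background composition over the 20 standard letters
#' @return A [background_freqs()] vector.
#' @export
uniform_freqs <- function() {
  background_freqs(setNames(rep(1 / 20, 20), STANDARD_AA))
}

# check local-alignment admissibility of a matrix under given frequencies:
# negative expected score and at least one positive score
check_admissible <- function(matrix, freqs) {
  letters <- names(freqs)
  missing <- setdiff(letters, matrix$alphabet)
  if (length(missing) > 0) {
    stop("matrix lacks letters present in the background: ",
         paste(missing, collapse = ", "))
  }
  S <- matrix$scores[letters, letters]
  ex <- as.numeric(t(freqs) %*% S %*% freqs)
  if (max(S) <= 0) {
    stop("inadmissible matrix: no positive score under the background alphabet")
  }
  if (ex >= 0) {
    stop("inadmissible matrix: expected score ", signif(ex, 4),
         " is not negative under the background frequencies")
  }
  invisible(ex)
}

#' Ungapped Karlin-Altschul lambda
#'
#' The unique positive root of sum_ij p_i p_j exp(lambda * s_ij) = 1,
#' found by bracketed root-finding to a residual below 1e-10.
#'
#' @param matrix a `substitution_matrix` (or name resolvable by
#'   [builtin_matrix()]).
#' @param freqs a [background_freqs()] vector.
#' @return Positive numeric lambda, per score unit.
#' @export
ungapped_lambda <- function(matrix, freqs = default_freqs()) {
  matrix <- builtin_matrix(matrix)
  check_admissible(matrix, freqs)
  letters <- names(freqs)
  S <- matrix$scores[letters, letters]
  pp <- as.numeric(outer(freqs, freqs))
  sv <- as.numeric(S)
  g <- function(lambda) sum(pp * exp(lambda * sv)) - 1
  hi <- 1
  while (g(hi) < 0) hi <- hi * 2
  lam <- uniroot(g, c(1e-12, hi), tol = 1e-14)$root
  if (abs(g(lam)) >= 1e-10) {
    # polish with Newton steps on the defining equation
    for (k in 1:50) {
      gp <- sum(pp * sv * exp(lam * sv))
      lam <- lam - g(lam) / gp
      if (abs(g(lam)) < 1e-12) break
    }
  }
  if (abs(g(lam)) >= 1e-10) stop("lambda root finding did not converge")
  lam
}

#' Gumbel parameters of a scoring scheme
#' @param lambda positive decay rate per score unit.
#' @param K positive prefactor.
#' @param source provenance tag, `"ungapped-analytic"` or `"gapped-simulated"`.
#' @return A `gumbel_params` object.
#' @export
gumbel_params <- function(lambda, K, source = "gapped-simulated") {
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  if (!is.finite(K) || K <= 0) stop("K must be positive")
  structure(list(lambda = lambda, K = K, source = source),
            class = "gumbel_params")
}

#' @export
print.gumbel_params <- function(x, ...) {
  cat(sprintf("gumbel_params: lambda = %.6g, K = %.6g (%s)\n",
              x$lambda, x$K, x$source))
  invisible(x)
}

#' Monte-Carlo Gumbel calibration for a gapped scoring scheme
#'
#' Simulates `n_pairs` i.i.d. random sequence pairs of length `seq_len`
#' from the background composition, computes their optimal local alignment
#' scores, and fits a Gumbel distribution by the method of moments:
#' lambda = pi / (sd * sqrt(6)) and K from the location parameter via
#' mu = log(K m n) / lambda. Deterministic given `seed`.
#'
#' @param matrix substitution matrix (or resolvable name).
#' @param gaps [gap_penalties()].
#' @param freqs [background_freqs()].
#' @param n_pairs number of simulated pairs (>= 100).
#' @param seq_len length of each simulated sequence (>= 50).
#' @param seed RNG seed.
#' @return A [gumbel_params()] with source `"gapped-simulated"`.
#' @export
calibrate_gapped <- function(matrix, gaps, freqs = default_freqs(),
                             n_pairs = 1000L, seq_len = 200L, seed = 1L) {
  matrix <- builtin_matrix(matrix)
  check_admissible(matrix, freqs)
  if (n_pairs < 100) stop("n_pairs must be at least 100")
  if (seq_len < 50) stop("seq_len must be at least 50")
  letters <- names(freqs)
  if (any(is.na(match(letters, RESIDUE_ALPHABET)))) {
    stop("background letters outside the protein alphabet: ",
         paste(setdiff(letters, RESIDUE_ALPHABET), collapse = ", "))
  }
  codes <- match(letters, RESIDUE_ALPHABET) - 1L
  S <- score_table(matrix)
  scores <- with_seed(seed, {
    as_list <- function() {
      lapply(seq_len(n_pairs), function(i) {
        codes[sample.int(length(codes), seq_len, replace = TRUE, prob = freqs)]
      })
    }
    a <- as_list(); b <- as_list()
    cpp_pair_scores(a, b, S, gaps$open, gaps$extend)
  })
  mu_hat <- mean(scores)
  sd_hat <- sd(scores)
  lambda <- pi / (sd_hat * sqrt(6))
  if (!is.finite(lambda) || lambda <= 0) {
    stop("degenerate Gumbel fit (lambda <= 0); increase n_pairs or seq_len")
  }
  euler <- 0.5772156649015329
  mu <- mu_hat - euler / lambda
  K <- exp(lambda * mu) / (as.numeric(seq_len) * seq_len)
  gumbel_params(lambda, K, source = "gapped-simulated")
}

#' E-value of an alignment score
#'
#' E = K * query_len * db_len * exp(-lambda * score): the expected number
#' of chance alignments scoring at least `score` in a search of a query of
#' `query_len` residues against `db_len` library residues.
#'
#' @param score alignment score in matrix units (vectorised).
#' @param params [gumbel_params()].
#' @param query_len query length in residues.
#' @param db_len total library residues.
#' @return Numeric E-value(s).
#' @export
evalue <- function(score, params, query_len, db_len) {
  stopifnot(query_len > 0, db_len > 0)
  params$K * as.numeric(query_len) * as.numeric(db_len) *
    exp(-params$lambda * as.numeric(score))
}

# expand a substitution matrix to the canonical index alphabet, falling back
# to the matrix's X column for letters it lacks, or to -1 if it has no X row
score_table <- function(matrix) {
  src <- matrix$scores
  n <- length(RESIDUE_ALPHABET)
  out <- matrix(-1L, n, n, dimnames = list(RESIDUE_ALPHABET, RESIDUE_ALPHABET))
  pos <- match(RESIDUE_ALPHABET, matrix$alphabet)
  if ("X" %in% matrix$alphabet) pos[is.na(pos)] <- match("X", matrix$alphabet)
  have <- !is.na(pos)
  out[have, have] <- src[pos[have], pos[have]]
  storage.mode(out) <- "integer"
  out
}
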