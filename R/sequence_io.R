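#' Construct a protein sequence collection
#'
#' A `protein_set` is a data frame with one row per sequence and columns
#' `id` (unique, non-empty), `desc` (free text) and `seq` (uppercase
#' residues over the 20 standard amino-acid letters plus the ambiguity
#' letters B, Z, X, U). `*` and `.` characters are mapped to X with a
#' warning; lower-case input is uppercased.
#'
#' @param id character vector of unique identifiers.
#' @param seq character vector of residue strings.
#' @param desc optional character vector of descriptions.
#' @return A `protein_set` data frame.
#' @export
protein_set <- function(id, seq, desc = "") {
  id <- as.character(id)
  seq <- as.character(seq)
  desc <- rep_len(as.character(desc), length(seq))
  stopifnot(length(id) == length(seq))
  if (length(id) == 0) {
    out <- data.frame(id = character(), desc = character(), seq = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("protein_set", "data.frame")
    return(out)
  }
  if (any(!nzchar(id))) stop("sequence ids must be non-empty")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  seq <- toupper(seq)
  if (any(grepl("[*.]", seq))) {
    warning("'*' and '.' characters mapped to X")
    seq <- gsub("[*.]", "X", seq)
  }
  empty <- !nzchar(seq)
  if (any(empty)) {
    stop("record '", id[which(empty)[1]], "' has an empty sequence")
  }
  bad <- regexpr(sprintf("[^%s]", paste(RESIDUE_ALPHABET, collapse = "")), seq)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("illegal character '", substr(seq[i], bad[i], bad[i]),
         "' in record '", id[i], "' at position ", bad[i])
  }
  out <- data.frame(id = id, desc = desc, seq = seq, stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

#' @export
print.protein_set <- function(x, ...) {
  cat("protein_set with", nrow(x), "sequence(s)\n")
  if (nrow(x) > 0) {
    shown <- head(x, 6)
    cat(sprintf("  %s (%d aa)\n", shown$id, nchar(shown$seq)), sep = "")
    if (nrow(x) > 6) cat("  ...\n")
  }
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Record ids are the first whitespace-delimited token of each header, the
#' remainder becomes the description. Residues are uppercased and validated
#' against the protein alphabet; `*`/`.` are mapped to X with a warning.
#'
#' @param path path to a FASTA file.
#' @return A [protein_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) {
    warning("no FASTA records in ", path)
    return(protein_set(character(), character()))
  }
  headers <- names(recs)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  protein_set(id, as.character(recs), desc)
}

#' Write protein sequences to a FASTA file
#'
#' @param records a [protein_set()].
#' @param path output path.
#' @param width residues per sequence line.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(inherits(records, "protein_set"), width >= 1)
  seqs <- Biostrings::BStringSet(records$seq)
  names(seqs) <- ifelse(nzchar(records$desc),
                        paste(records$id, records$desc),
                        records$id)
  Biostrings::writeXStringSet(seqs, path, width = as.integer(width))
  invisible(path)
}

#' Read SCOP-style homology labels
#'
#' Tab-separated file with columns sequence id, fold id, superfamily id;
#' `#` comment lines are ignored. Every superfamily must nest inside a
#' single fold, and an id may not appear twice with different labels.
#'
#' @param path path to the labels TSV.
#' @return A `homology_labels` data frame with columns `id`, `fold`,
#'   `superfamily`.
#' @export
read_labels <- function(path) {
  d <- read.delim(path, header = FALSE, comment.char = "#",
                  colClasses = "character", col.names = c("id", "fold", "superfamily"))
  homology_labels(d$id, d$fold, d$superfamily)
}

#' Construct homology labels
#'
#' @param id,fold,superfamily character vectors of equal length.
#' @return A `homology_labels` data frame.
#' @export
homology_labels <- function(id, fold, superfamily) {
  d <- unique(data.frame(id = as.character(id), fold = as.character(fold),
                         superfamily = as.character(superfamily),
                         stringsAsFactors = FALSE))
  if (anyDuplicated(d$id)) {
    stop("id(s) with conflicting labels: ",
         paste(unique(d$id[duplicated(d$id)]), collapse = ", "))
  }
  span <- tapply(d$fold, d$superfamily, function(f) length(unique(f)))
  if (any(span > 1)) {
    stop("superfamily spanning multiple folds: ",
         paste(names(span)[span > 1], collapse = ", "))
  }
  class(d) <- c("homology_labels", "data.frame")
  d
}

#' Read an exclusion-pair rule set
#'
#' Tab-separated unordered pairs of classification ids (fold- or
#' superfamily-level tokens) whose cross hits are not counted as false
#' positives; `#` comment lines are ignored.
#'
#' @param path path to the exclusion TSV.
#' @return An `exclusion_rules` object.
#' @export
read_exclusions <- function(path) {
  d <- read.delim(path, header = FALSE, comment.char = "#",
                  colClasses = "character", col.names = c("a", "b"))
  exclusion_rules(d$a, d$b)
}

#' Construct exclusion rules from paired classification ids
#'
#' @param a,b character vectors: unordered pairs of distinct classification ids.
#' @return An `exclusion_rules` object (a set of canonical pair keys).
#' @export
exclusion_rules <- function(a = character(), b = character()) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(length(a) == length(b))
  if (any(a == b)) {
    stop("exclusion pairs must reference distinct classifications: ",
         paste(unique(a[a == b]), collapse = ", "))
  }
  keys <- unique(paste(pmin(a, b), pmax(a, b), sep = "\t"))
  structure(list(keys = keys), class = "exclusion_rules")
}

#' @export
print.exclusion_rules <- function(x, ...) {
  cat("exclusion_rules with", length(x$keys), "pair(s)\n")
  invisible(x)
}

#' Read reference alignments as residue-pair tables
#'
#' Tab-separated columns: query id, target id, 0-based query residue index,
#' 0-based target residue index; one aligned residue pair per row.
#'
#' @param path path to the reference-alignment TSV.
#' @return A data frame with columns `query_id`, `target_id`, `qpos`, `tpos`.
#' @export
read_ref_pairs <- function(path) {
  d <- read.delim(path, header = FALSE, comment.char = "#",
                  col.names = c("query_id", "target_id", "qpos", "tpos"),
                  colClasses = c("character", "character", "integer", "integer"))
  d
}

#' Write reference alignments
#' @param refs data frame as returned by [read_ref_pairs()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_ref_pairs <- function(refs, path) {
  write.table(refs[, c("query_id", "target_id", "qpos", "tpos")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# encode residue strings as 0-based codes into the canonical index alphabet
encode_residues <- function(seq) {
  lapply(strsplit(seq, ""), function(ch) {
    match(ch, RESIDUE_ALPHABET) - 1L
  })
}
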