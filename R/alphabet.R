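#' @useDynLib acsarch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# The 20 standard amino-acid letters, in the fixed column order used by
# every matrix in the package.
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Letters treated as ambiguous: scored as zero log-odds when scanning,
# excluded from counts when building models or backgrounds.
AA_AMBIGUOUS <- c("X", "B", "Z", "J", "U", "O", "*")

#' Encode a protein sequence as letter indices
#'
#' Internal helper: maps each character to its index in the standard
#' 20-letter alphabet (column order `A C D E ... Y`), with 0 for ambiguous
#' letters (X, B, Z, J, U, O, `*`). Unknown characters are an error.
#'
#' @param x a single character string.
#' @return integer vector, one element per residue.
#' @keywords internal
encode_seq <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  idx <- match(ch, AA_LETTERS)
  amb <- is.na(idx) & ch %in% AA_AMBIGUOUS
  if (any(is.na(idx) & !amb)) {
    bad <- unique(ch[is.na(idx) & !amb])
    stop("non-amino-acid letters in sequence: ", paste(bad, collapse = " "))
  }
  idx[is.na(idx)] <- 0L
  idx
}

decode_seq <- function(idx) {
  out <- rep("X", length(idx))
  out[idx > 0L] <- AA_LETTERS[idx[idx > 0L]]
  paste(out, collapse = "")
}

# Coerce FASTA-ish inputs (AAStringSet, named character vector) to a named
# character vector of upper-case sequences with '*' stops stripped.
as_seq_vector <- function(x) {
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  stopifnot(is.character(x))
  if (length(x) == 0L) return(stats::setNames(character(0), character(0)))
  out <- toupper(gsub("\\*", "", x))
  if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
  out
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning a named
#' character vector; `*` stop symbols are stripped and identifiers are
#' truncated at the first whitespace.
#'
#' @param path path to a FASTA file (wrapped or single-line).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- as_seq_vector(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(as_seq_vector(seqs))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
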