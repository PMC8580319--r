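#' Estimate a background amino-acid composition
#'
#' Maximum-likelihood letter frequencies over the 20 standard amino acids
#' with a +1 pseudocount per letter, so no frequency is ever zero. The
#' background is the null model for motif log-odds scores and for the
#' exact p-values of [score_distribution()]. Ambiguous letters
#' (X, B, Z, J, U, O, `*`) are excluded from counting.
#'
#' @param sequences character vector (or `AAStringSet`) of protein
#'   sequences; at least one standard residue is required.
#' @return an object of class `acs_background`: a named numeric vector of
#'   20 probabilities summing to 1.
#' @examples
#' estimate_background(c("ACDEFGHIKLMNPQRSTVWY"))
#' @export
estimate_background <- function(sequences) {
  seqs <- as_seq_vector(sequences)
  if (length(seqs) == 0L) stop("no sequences: cannot estimate a background")
  idx <- unlist(lapply(seqs, encode_seq), use.names = FALSE)
  idx <- idx[idx > 0L]
  if (length(idx) == 0L)
    stop("input contains zero standard residues: unusable background")
  counts <- tabulate(idx, nbins = 20L) + 1
  freq <- counts / sum(counts)
  names(freq) <- AA_LETTERS
  structure(freq, class = "acs_background")
}

#' Uniform background over the 20 standard amino acids
#'
#' @return an `acs_background` with every frequency 1/20.
#' @export
uniform_background <- function() {
  structure(stats::setNames(rep(1 / 20, 20), AA_LETTERS),
            class = "acs_background")
}

as_background <- function(background) {
  if (inherits(background, "acs_background")) return(background)
  stopifnot(is.numeric(background), length(background) == 20)
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  if (any(background <= 0)) stop("background frequencies must be > 0")
  structure(stats::setNames(as.numeric(background), AA_LETTERS),
            class = "acs_background")
}

#' @export
print.acs_background <- function(x, ...) {
  cat("Amino-acid background (20 letters)\n")
  print(round(unclass(x), 4))
  invisible(x)
}
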