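#' Exact null distribution of a motif's window score
#'
#' Computes, by column-wise convolution over the background, the exact
#' probability mass function of the integer-quantised window score of a
#' motif under the null that every window letter is drawn independently
#' from the background. Log-odds scores (bits) are scaled by `scale` bins
#' per bit and rounded down, so the resulting tail p-values are
#' conservative. This is the position p-value machinery of motif-search
#' tools such as MAST.
#'
#' @param motif an `acs_motif`, or a numeric log-odds matrix
#'   (width x alphabet) for toy alphabets.
#' @param background background frequencies; defaults to the motif's own.
#'   Must match the number of matrix columns.
#' @param scale integer score bins per bit (default 1000).
#' @return an object of class `acs_score_dist` with elements `pmf`
#'   (named by integer score), `offset` (minimum total score), `scale`,
#'   and `tail` (upper-tail probabilities aligned with `pmf`).
#' @examples
#' bg <- uniform_background()
#' m <- build_motif_model(c("ACDEFG"), bg, pseudocount = 0.375)
#' d <- score_distribution(m, bg)
#' sum(d$pmf)
#' @export
score_distribution <- function(motif, background = NULL, scale = 1000L) {
  if (inherits(motif, "acs_motif")) {
    if (is.null(background)) background <- motif$background
    bg <- as.numeric(as_background(background))
    q <- quantise_motif(motif, scale)
  } else {
    stopifnot(is.matrix(motif))
    if (is.null(background)) stop("background required for a raw matrix")
    bg <- as.numeric(background)
    stopifnot(length(bg) == ncol(motif), abs(sum(bg) - 1) < 1e-9)
    v <- floor(motif * scale)
    v[!is.finite(v) | v < -100 * scale] <- -100 * scale
    q <- matrix(as.integer(v), nrow = nrow(motif))
  }
  res <- cpp_score_pmf(q, bg)
  pmf <- res$pmf
  if (abs(sum(pmf) - 1) > 1e-9) stop("pmf mass != 1")
  tail <- rev(cumsum(rev(pmf)))
  structure(list(pmf = pmf, offset = res$offset, scale = scale,
                 tail = tail),
            class = "acs_score_dist")
}

#' Exact position p-value of an integer-quantised window score
#'
#' Probability that a background window scores at least `qscore` (on the
#' integer grid of `dist`).
#'
#' @param dist an `acs_score_dist` from [score_distribution()].
#' @param qscore integer-quantised score(s).
#' @return p-value(s) in (0, 1].
#' @export
score_pvalue <- function(dist, qscore) {
  i <- qscore - dist$offset + 1
  n <- length(dist$tail)
  p <- ifelse(i <= 0, 1, ifelse(i > n, 0, dist$tail[pmax(pmin(i, n), 1)]))
  # scores above the maximum achievable have p 0; report smallest mass
  # instead so the invariant 0 < p <= 1 holds
  pmin(pmax(p, .Machine$double.xmin), 1)
}
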