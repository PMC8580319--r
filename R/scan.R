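#' Scan a sequence with a motif
#'
#' Scores every window of the sequence with the motif's log-odds matrix
#' and keeps windows whose exact position p-value (see
#' [score_distribution()]) is at or below `p_threshold`. Ambiguous
#' letters contribute zero log-odds; windows more than 50% ambiguous are
#' skipped. Coordinates are 1-based inclusive.
#'
#' @param sequence a protein sequence (single string).
#' @param motif an `acs_motif`.
#' @param background background model; defaults to the motif's.
#' @param p_threshold position p-value cutoff (default `1e-4`).
#' @param sequence_id identifier used in the output (default "seq").
#' @param dist optional precomputed `acs_score_dist` for this motif.
#' @return a data.frame of hits with columns `sequence_id`, `motif_id`,
#'   `start`, `end`, `score_bits`, `p_value`, sorted by `start`. A
#'   sequence shorter than the motif yields zero rows with a warning.
#' @export
scan_sequence <- function(sequence, motif, background = NULL,
                          p_threshold = 1e-4, sequence_id = "seq",
                          dist = NULL) {
  stopifnot(inherits(motif, "acs_motif"))
  if (is.null(background)) background <- motif$background
  background <- as_background(background)
  empty <- data.frame(sequence_id = character(0), motif_id = character(0),
                      start = integer(0), end = integer(0),
                      score_bits = numeric(0), p_value = numeric(0))
  seq_chr <- as_seq_vector(sequence)[[1]]
  if (nchar(seq_chr) < motif$width) {
    warning("sequence ", sequence_id, " shorter than motif ",
            motif$motif_id, "; no windows to scan")
    return(empty)
  }
  if (is.null(dist)) dist <- score_distribution(motif, background)
  q <- quantise_motif(motif, dist$scale)
  res <- cpp_window_scores(encode_seq(seq_chr), motif$log_odds, q, 0.5)
  keep <- !res$skipped
  p <- score_pvalue(dist, res$qscore)
  keep <- keep & p <= p_threshold
  if (!any(keep)) return(empty)
  starts <- which(keep)
  data.frame(sequence_id = sequence_id, motif_id = motif$motif_id,
             start = starts, end = starts + motif$width - 1L,
             score_bits = res$bits[keep], p_value = p[keep])
}

#' Best hit of a motif in a sequence, with a sequence-level p-value
#'
#' Returns the lowest-p-value window together with a MAST-style
#' sequence-level p-value, the Sidak correction
#' `1 - (1 - p_position)^m` over the `m` scanned windows.
#'
#' @inheritParams scan_sequence
#' @return one-row data.frame (columns of [scan_sequence()] plus
#'   `seq_p_value`), or zero rows if nothing is scorable.
#' @export
best_hit <- function(sequence, motif, background = NULL,
                     sequence_id = "seq", dist = NULL) {
  hits <- scan_sequence(sequence, motif, background, p_threshold = 1,
                        sequence_id = sequence_id, dist = dist)
  if (nrow(hits) == 0L) return(hits)
  m <- nrow(hits)
  best <- hits[order(hits$p_value, hits$start)[1], , drop = FALSE]
  best$seq_p_value <- 1 - (1 - best$p_value)^m
  rownames(best) <- NULL
  best
}

#' Scan a sequence with a set of motifs
#'
#' @param sequence protein sequence.
#' @param motifs named list of `acs_motif` objects.
#' @param background shared background (default: first motif's).
#' @param p_threshold position p-value cutoff.
#' @param sequence_id identifier for the output.
#' @param dists optional named list of precomputed score distributions.
#' @return data.frame of hits across all motifs, sorted by start.
#' @export
scan_motifs <- function(sequence, motifs, background = NULL,
                        p_threshold = 1e-4, sequence_id = "seq",
                        dists = NULL) {
  stopifnot(length(motifs) > 0)
  out <- lapply(names(motifs), function(id) {
    scan_sequence(sequence, motifs[[id]], background, p_threshold,
                  sequence_id,
                  dist = if (!is.null(dists)) dists[[id]] else NULL)
  })
  out <- do.call(rbind, out)
  out[order(out$start, out$motif_id), , drop = FALSE]
}

#' Assess the ordered nine-motif ACS architecture
#'
#' Given scan hits for one sequence, keeps the lowest-p-value hit per
#' required motif (ties broken by smaller start) and decides whether the
#' sequence carries the complete architecture: all required motifs
#' present, best hits at strictly increasing starts in motif order, and
#' no two kept hits overlapping. The AAT motif is flagged independently
#' and never vetoes completeness.
#'
#' @param hits data.frame of hits (as from [scan_motifs()]) for a single
#'   sequence.
#' @param required_set character vector of required motif ids, in
#'   architectural order (default `ACS1`..`ACS9`).
#' @param aat_id motif id reported independently (default `"AAT"`).
#' @return an object of class `acs_architecture`: list with
#'   `sequence_id`, `presence` (named list of kept one-row hit frames or
#'   `NULL`), `ordered`, `aat_present`, `complete`.
#' @export
assess_architecture <- function(hits, required_set = paste0("ACS", 1:9),
                                aat_id = "AAT") {
  sequence_id <- if (nrow(hits)) unique(hits$sequence_id) else NA_character_
  if (length(sequence_id) > 1)
    stop("hits must refer to a single sequence; got: ",
         paste(sequence_id, collapse = ", "))
  keep_best <- function(id) {
    h <- hits[hits$motif_id == id, , drop = FALSE]
    if (nrow(h) == 0L) return(NULL)
    h[order(h$p_value, h$start)[1], , drop = FALSE]
  }
  presence <- stats::setNames(lapply(required_set, keep_best), required_set)
  kept <- presence[!vapply(presence, is.null, logical(1))]
  starts <- vapply(kept, function(h) as.numeric(h$start), numeric(1))
  ends <- vapply(kept, function(h) as.numeric(h$end), numeric(1))
  ordered <- TRUE
  if (length(kept) >= 2) {
    o <- order(match(names(kept), required_set))
    s <- starts[o]; e <- ends[o]
    increasing <- all(diff(s) > 0)
    # kept hits must be pairwise disjoint intervals
    ivl_s <- sort(starts)
    ivl_e <- ends[order(starts)]
    disjoint <- all(utils::head(ivl_e, -1) < ivl_s[-1])
    ordered <- increasing && disjoint
  }
  complete <- length(kept) == length(required_set) && ordered
  aat <- keep_best(aat_id)
  structure(list(sequence_id = sequence_id, presence = presence,
                 ordered = ordered, aat_present = !is.null(aat),
                 aat_hit = aat, complete = complete),
            class = "acs_architecture")
}

#' @export
print.acs_architecture <- function(x, ...) {
  flags <- vapply(x$presence, Negate(is.null), logical(1))
  cat(sprintf("Architecture of %s: [%s] ordered=%s AAT=%s complete=%s\n",
              x$sequence_id,
              paste(ifelse(flags, "+", "-"), collapse = ""),
              x$ordered, x$aat_present, x$complete))
  invisible(x)
}
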