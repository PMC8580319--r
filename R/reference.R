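#' The synthetic AtACS7-like reference sequence
#'
#' Loads the reference used for key-residue mapping when no real
#' reference is supplied. This is a generator-built synthetic stand-in
#' for the AtACS7 sequence (TAIR AT4G26200), not the real protein: it
#' carries the nine ACS motifs in order with the key glutamine at
#' position 98 and the key asparagine at position 217 by construction,
#' so that the canonical requirement set `c("98" = "Q", "217" = "N")`
#' applies unchanged. Drop in the real AtACS7 sequence (initiator Met
#' as residue 1) wherever real data are analysed.
#'
#' @return list with `sequence` (character), `id`, `q_pos` (98),
#'   `n_pos` (217).
#' @export
synthetic_reference <- function() {
  path <- system.file("extdata", "atacs7_like_synthetic.fasta",
                      package = "acsarch")
  s <- read_fasta(path)
  list(sequence = unname(s[[1]]), id = names(s)[1],
       q_pos = 98L, n_pos = 217L)
}
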