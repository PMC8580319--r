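#' Simulate, train, and classify a synthetic benchmark
#'
#' End-to-end driver used by the analysis scripts and the acceptance
#' checks: samples a training family and an evaluation family from the
#' same specification (different seeds), builds the motif library from
#' the training family's planted instances, and classifies the
#' evaluation family against its reference with the genuine-ACS rule.
#'
#' @param spec an [family_spec()].
#' @param seed integer seed; the training family uses `seed + 1`.
#' @param config an [acs_config()].
#' @return list with `family` (evaluation `acs_family`), `train`,
#'   `motifs`, `batch` (`acs_evidence`), and `accuracy`.
#' @export
run_benchmark <- function(spec = family_spec(), seed,
                          config = acs_config()) {
  if (missing(seed)) stop("seed is required")
  family <- sample_family(spec, seed = seed)
  # independent training draw of the same family (same consensus set)
  train <- sample_family(spec, seed = seed + 1L,
                         consensus = family$consensus)
  motifs <- family_motifs(train)
  ref <- family$reference
  req <- stats::setNames(c("Q", "N"),
                         c(ref$q_pos, ref$n_pos))
  batch <- classify_batch(family$sequences, motifs, ref$sequence,
                          requirements = req, config = config)
  list(family = family, train = train, motifs = motifs, batch = batch,
       accuracy = classification_accuracy(batch, family$truth))
}

#' Render a combined human-readable report
#'
#' Assembles the +/- evidence table with, when available, the
#' phylogenetic monophyly verdict for the predicted positives and a
#' structural RMSD block; absent stages are marked "not run".
#'
#' @param batch an `acs_evidence` (required).
#' @param tree optional [ape::phylo] over (a subset of) the classified
#'   sequences.
#' @param struct_report optional data.frame of structural comparisons
#'   (e.g. from [reproduce_printed_rmsds()]).
#' @return character vector of report lines (also printed).
#' @export
render_report <- function(batch, tree = NULL, struct_report = NULL) {
  if (is.null(batch)) stop("classification artifact missing: run classify first")
  tab <- evidence_table(batch)
  lines <- c("== Evidence table ==",
             utils::capture.output(print(tab, row.names = FALSE)))
  lines <- c(lines, "", "== Phylogeny ==")
  if (is.null(tree)) {
    lines <- c(lines, "not run")
  } else {
    pos <- intersect(batch$sequence_id[batch$predicted_acs],
                     tree$tip.label)
    verdict <- if (length(pos) == 0) "no predicted positives in tree"
      else sprintf("predicted positives monophyletic: %s",
                   ifelse(is_monophyletic(tree, pos), "yes", "no"))
    lines <- c(lines, verdict)
  }
  lines <- c(lines, "", "== Structural comparisons ==")
  if (is.null(struct_report)) {
    lines <- c(lines, "not run")
  } else {
    lines <- c(lines, utils::capture.output(
      print(struct_report, row.names = FALSE)))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
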