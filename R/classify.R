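#' Classifier configuration
#'
#' Bundles the tunable thresholds of the genuine-ACS decision rule with
#' a stable content hash that is stamped into every output row, so a
#' table can always be traced to the exact settings that produced it.
#'
#' @param p_threshold position p-value for motif presence (default
#'   `1e-4`, the conventional motif-search position cutoff).
#' @param strict_n217 if `TRUE` (default) the asparagine requirement is
#'   a hard conjunct of the predicate; if `FALSE` its failure is only
#'   annotated (the two-level presentation in which the inactive
#'   motif-complete outlier is explained post hoc).
#' @param matrix,gap_open,gap_extend alignment parameters for the
#'   key-residue mapping.
#' @param scale PSSM integer score bins per bit.
#' @return list of class `acs_config` with a `hash` element.
#' @export
acs_config <- function(p_threshold = 1e-4, strict_n217 = TRUE,
                       matrix = "BLOSUM62", gap_open = 11,
                       gap_extend = 1, scale = 1000L) {
  cfg <- list(p_threshold = p_threshold, strict_n217 = strict_n217,
              matrix = matrix, gap_open = gap_open,
              gap_extend = gap_extend, scale = as.integer(scale))
  cfg <- cfg[order(names(cfg))]
  cfg$hash <- rlang::hash(cfg)
  class(cfg) <- "acs_config"
  cfg
}

#' Classify one sequence with the genuine-ACS rule
#'
#' Applies the decision rule: a sequence is predicted to be a genuine
#' ACS iff all nine ACS motifs are present at or below the position
#' p-value threshold, their best hits occur in architectural order
#' without overlap, and the residues corresponding to the key glutamine
#' (Q98) and asparagine (N217) of the reference both match. The
#' asparagine conjunct encodes the one known motif-complete inactive
#' outlier; when motifs and glutamine pass but the asparagine fails, an
#' exception note records it.
#'
#' @param sequence protein sequence (single string).
#' @param motifs named list of `acs_motif` containing `ACS1`..`ACS9`
#'   (an `AAT` model, if present, is reported but never vetoes).
#' @param reference reference sequence carrying the key-residue
#'   numbering.
#' @param requirements named letters at 1-based reference positions
#'   (default `c("98" = "Q", "217" = "N")`); the first entry is the
#'   glutamine-like requirement, the second the asparagine-like one.
#' @param config an [acs_config()].
#' @param background background model (default: first motif's).
#' @param sequence_id identifier.
#' @param dists optional named list of precomputed score distributions.
#' @return object of class `acs_classification`.
#' @export
classify_sequence <- function(sequence, motifs, reference,
                              requirements = c("98" = "Q", "217" = "N"),
                              config = acs_config(), background = NULL,
                              sequence_id = "seq", dists = NULL) {
  required <- paste0("ACS", 1:9)
  missing <- setdiff(required, names(motifs))
  if (length(missing))
    stop("motif set lacks required models: ",
         paste(missing, collapse = ", "))
  if (length(requirements) != 2)
    stop("exactly two key-residue requirements expected (Q-like, N-like)")
  hits <- scan_motifs(sequence, motifs, background,
                      p_threshold = config$p_threshold,
                      sequence_id = sequence_id, dists = dists)
  arch <- assess_architecture(hits, required_set = required)
  arch$sequence_id <- sequence_id
  kr <- check_key_residues(sequence, reference, requirements,
                           matrix = config$matrix,
                           gap_open = config$gap_open,
                           gap_extend = config$gap_extend)
  q_ok <- kr$status[1] == "match"
  n_ok <- kr$status[2] == "match"
  motifs_ok <- arch$complete
  predicted <- motifs_ok && q_ok && (n_ok || !config$strict_n217)
  notes <- character(0)
  if (motifs_ok && q_ok && !n_ok)
    notes <- c(notes, sprintf(
      "motif-complete with the key glutamine but lacking the %s%d asparagine equivalent (inactive-outlier case)",
      kr$required[2], kr$position[2]))
  notes <- c(notes, "C-beta-S lyase activity: not determined by this model")
  structure(list(sequence_id = sequence_id,
                 motif_presence = vapply(arch$presence, Negate(is.null),
                                         logical(1)),
                 aat_present = arch$aat_present, ordered = arch$ordered,
                 q98 = list(status = kr$status[1],
                            letter = kr$query_letter[1],
                            position = kr$query_position[1]),
                 n217 = list(status = kr$status[2],
                             letter = kr$query_letter[2],
                             position = kr$query_position[2]),
                 predicted_acs = predicted, exception_notes = notes,
                 architecture = arch, key_residues = kr, hits = hits,
                 config_hash = config$hash),
            class = "acs_classification")
}

#' @export
print.acs_classification <- function(x, ...) {
  cat(sprintf("%s: motifs [%s] AAT=%s ordered=%s Q=%s N=%s -> %s\n",
              x$sequence_id,
              paste(ifelse(x$motif_presence, "+", "-"), collapse = ""),
              ifelse(x$aat_present, "+", "-"), x$ordered,
              x$q98$status, x$n217$status,
              if (x$predicted_acs) "genuine ACS" else "not ACS"))
  invisible(x)
}

#' Classify a batch of sequences into an evidence table
#'
#' Runs [classify_sequence()] on every record and assembles the
#' per-sequence evidence matrix: one row per sequence with the nine
#' motif flags, the AAT flag, order, key-residue statuses, and the
#' prediction. Duplicate sequence identifiers are an error; an empty
#' input yields an empty table with a warning.
#'
#' @param sequences named character vector / `AAStringSet` (or a FASTA
#'   path).
#' @param motifs named list of `acs_motif` with `ACS1`..`ACS9`.
#' @param reference reference sequence for key-residue mapping.
#' @param requirements key-residue requirements, see
#'   [classify_sequence()].
#' @param config an [acs_config()].
#' @param background optional shared background.
#' @return data.frame of class `acs_evidence` with columns
#'   `sequence_id`, `ACS1`..`ACS9`, `AAT`, `ordered`, `Q98`, `N217`,
#'   `predicted_acs` (logicals/status strings), `notes`, `config_hash`;
#'   the full classification objects are attached as
#'   `attr(, "classifications")`.
#' @export
classify_batch <- function(sequences, motifs, reference,
                           requirements = c("98" = "Q", "217" = "N"),
                           config = acs_config(), background = NULL) {
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences) && is.null(names(sequences)))
    sequences <- read_fasta(sequences)
  seqs <- as_seq_vector(sequences)
  cols <- c("sequence_id", paste0("ACS", 1:9), "AAT", "ordered", "Q98",
            "N217", "predicted_acs", "notes", "config_hash")
  if (length(seqs) == 0) {
    warning("empty input: empty evidence table")
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
    class(out) <- c("acs_evidence", class(out))
    return(out)
  }
  dup <- names(seqs)[duplicated(names(seqs))]
  if (length(dup))
    stop("duplicate sequence ids: ", paste(unique(dup), collapse = ", "))
  if (is.null(background)) background <- motifs[[1]]$background
  dists <- lapply(motifs, score_distribution, background = background,
                  scale = config$scale)
  cls <- lapply(names(seqs), function(id)
    classify_sequence(seqs[[id]], motifs, reference, requirements,
                      config = config, background = background,
                      sequence_id = id, dists = dists))
  status_sym <- function(kr)
    switch(kr$status, match = "+", deleted = "del", kr$letter)
  out <- do.call(rbind, lapply(cls, function(x) {
    row <- data.frame(sequence_id = x$sequence_id)
    for (k in 1:9) row[[paste0("ACS", k)]] <- x$motif_presence[[k]]
    row$AAT <- x$aat_present
    row$ordered <- x$ordered
    row$Q98 <- status_sym(x$q98)
    row$N217 <- status_sym(x$n217)
    row$predicted_acs <- x$predicted_acs
    row$notes <- paste(x$exception_notes, collapse = "; ")
    row$config_hash <- x$config_hash
    row
  }))
  attr(out, "classifications") <- cls
  class(out) <- c("acs_evidence", class(out))
  out
}

#' Render an evidence table with +/- glyphs
#'
#' @param batch an `acs_evidence` table from [classify_batch()].
#' @return data.frame of characters: `+` for presence/prediction, `-`
#'   for absence, letters for key-residue mismatches, `del` for
#'   deletions.
#' @export
evidence_table <- function(batch) {
  sym <- function(v) ifelse(v, "+", "-")
  out <- data.frame(sequence_id = batch$sequence_id)
  for (k in paste0("ACS", 1:9)) out[[k]] <- sym(batch[[k]])
  out$AAT <- sym(batch$AAT)
  out$ordered <- sym(batch$ordered)
  out$Q98 <- batch$Q98
  out$N217 <- batch$N217
  out$predicted_ACS <- sym(batch$predicted_acs)
  out
}

#' Write an evidence table (TSV) and its JSON hit report
#'
#' @param batch an `acs_evidence`.
#' @param tsv_path output TSV of the +/- table.
#' @param json_path optional output JSON with full hit coordinates and
#'   p-values per sequence.
#' @return `tsv_path`, invisibly.
#' @export
write_evidence <- function(batch, tsv_path, json_path = NULL) {
  utils::write.table(evidence_table(batch), tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    cls <- attr(batch, "classifications")
    rep <- lapply(cls, function(x)
      list(sequence_id = x$sequence_id,
           predicted_acs = x$predicted_acs,
           q98 = x$q98, n217 = x$n217,
           hits = x$hits, notes = x$exception_notes,
           config_hash = x$config_hash))
    names(rep) <- vapply(cls, `[[`, "", "sequence_id")
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(tsv_path)
}

#' Accuracy of predictions against ground truth
#'
#' @param batch an `acs_evidence`.
#' @param truth data.frame with `sequence_id` and `is_positive` (as in
#'   an `acs_family`'s `truth`).
#' @return fraction of sequences whose prediction matches the label.
#' @export
classification_accuracy <- function(batch, truth) {
  m <- match(batch$sequence_id, truth$sequence_id)
  if (anyNA(m)) stop("truth is missing some sequence ids")
  mean(batch$predicted_acs == truth$is_positive[m])
}
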