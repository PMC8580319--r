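#' Fetch a protein substitution matrix
#'
#' Loads one of the substitution matrices shipped with Biostrings
#' (BLOSUM45/50/62/80/100, PAM30/40/70/120/250) as an integer matrix.
#'
#' @param name matrix name, default `"BLOSUM62"`.
#' @return symmetric integer score matrix with letter dimnames.
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- get(name, envir = e)
  stopifnot(isTRUE(all.equal(m, t(m))))
  m
}

# Map residue characters onto the rows of a substitution matrix,
# folding letters the matrix lacks (U, O, J, ...) onto X.
subst_lookup <- function(ch, m) {
  ch[!ch %in% rownames(m)] <- "X"
  ch
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch-style global alignment (end gaps penalised) with
#' affine gap costs: a gap of length `k` costs
#' `gap_open + k * gap_extend`. The traceback is deterministic with
#' tie-break diagonal > up > left (up consumes a query residue).
#' Ambiguous letters are scored via the matrix's `X` row.
#'
#' @param query,reference protein sequences (single strings).
#' @param matrix substitution matrix (name or matrix), default BLOSUM62.
#' @param gap_open,gap_extend gap parameters (defaults 11 and 1).
#' @param query_id,reference_id identifiers stored in the result.
#' @return an object of class `acs_alignment`: list with `query_id`,
#'   `reference_id`, `aligned_query`, `aligned_reference` (equal-length
#'   gapped strings), `score`, and the index maps `query_index`,
#'   `reference_index` (0 = gap).
#' @export
global_align <- function(query, reference, matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1,
                         query_id = "query", reference_id = "reference") {
  if (is.character(matrix) && length(matrix) == 1) {
    matrix <- substitution_matrix(matrix)
  }
  q <- as_seq_vector(query)[[1]]
  r <- as_seq_vector(reference)[[1]]
  if (nchar(q) == 0 || nchar(r) == 0) stop("empty sequence")
  qc <- subst_lookup(strsplit(q, "")[[1]], matrix)
  rc <- subst_lookup(strsplit(r, "")[[1]], matrix)
  S <- matrix[qc, rc, drop = FALSE]
  res <- cpp_profile_align(S, gap_open, gap_extend)
  qa <- ifelse(res$a == 0, "-", strsplit(q, "")[[1]][pmax(res$a, 1)])
  ra <- ifelse(res$b == 0, "-", strsplit(r, "")[[1]][pmax(res$b, 1)])
  structure(list(query_id = query_id, reference_id = reference_id,
                 aligned_query = paste(qa, collapse = ""),
                 aligned_reference = paste(ra, collapse = ""),
                 score = res$score,
                 query_index = res$a, reference_index = res$b),
            class = "acs_alignment")
}

#' @export
print.acs_alignment <- function(x, ...) {
  cat(sprintf("Global alignment %s vs %s, score %.1f\n",
              x$query_id, x$reference_id, x$score))
  cat(substr(x$aligned_query, 1, 60), "...\n")
  cat(substr(x$aligned_reference, 1, 60), "...\n")
  invisible(x)
}

#' Map a reference position through an alignment
#'
#' Locates the alignment column holding the reference residue at 1-based
#' position `ref_pos` and reports the corresponding query residue and
#' position, or "deleted" when the query has a gap in that column.
#'
#' @param alignment an `acs_alignment` from [global_align()].
#' @param ref_pos 1-based reference position.
#' @return list with `reference_position`, `reference_residue`,
#'   `query_position` (NA if deleted), `query_residue` (NA if deleted).
#' @export
map_reference_position <- function(alignment, ref_pos) {
  ri <- alignment$reference_index
  if (ref_pos < 1 || ref_pos > max(ri))
    stop("ref_pos ", ref_pos, " out of range 1..", max(ri))
  col <- which(ri == ref_pos)
  qa <- strsplit(alignment$aligned_query, "")[[1]]
  ra <- strsplit(alignment$aligned_reference, "")[[1]]
  qi <- alignment$query_index[col]
  list(reference_position = ref_pos, reference_residue = ra[col],
       query_position = if (qi == 0) NA_integer_ else qi,
       query_residue = if (qi == 0) NA_character_ else qa[col])
}

#' Key-residue status of a query relative to a reference
#'
#' Aligns the query globally to the reference and reports, for each
#' required position, whether the aligned query residue matches the
#' required letter ("match"), differs ("mismatch"), or falls in a
#' deletion ("deleted"). The defaults encode the two residues the
#' genuine-ACS model requires: the cross-subunit glutamine at reference
#' position 98 and the PLP-contacting asparagine at 217 (AtACS7
#' numbering, initiator Met = 1).
#'
#' @param query query protein sequence.
#' @param reference reference sequence carrying the canonical numbering.
#' @param requirements named character vector: names are 1-based
#'   reference positions, values required letters. Default
#'   `c("98" = "Q", "217" = "N")`.
#' @param ... passed to [global_align()].
#' @return data.frame with one row per requirement: `position`,
#'   `required`, `status`, `query_letter`, `query_position`.
#' @export
check_key_residues <- function(query, reference,
                               requirements = c("98" = "Q", "217" = "N"),
                               ...) {
  aln <- global_align(query, reference, ...)
  pos <- as.integer(names(requirements))
  rows <- lapply(seq_along(pos), function(k) {
    m <- map_reference_position(aln, pos[k])
    status <- if (is.na(m$query_residue)) "deleted"
      else if (m$query_residue == requirements[[k]]) "match"
      else "mismatch"
    data.frame(position = pos[k], required = requirements[[k]],
               status = status,
               query_letter = if (is.na(m$query_residue)) NA_character_
                              else m$query_residue,
               query_position = m$query_position)
  })
  out <- do.call(rbind, rows)
  attr(out, "alignment") <- aln
  out
}

#' Construct an N/C-terminal chimera of two proteins
#'
#' Concatenates `donor[1..donor_boundary]` with
#' `acceptor[acceptor_boundary..end]`, the construction used to graft an
#' N-terminal motif region onto a seven-motif backbone.
#'
#' @param n_donor sequence donating the N-terminus.
#' @param c_acceptor sequence donating the C-terminus.
#' @param donor_boundary 1-based last donor residue kept.
#' @param acceptor_boundary 1-based first acceptor residue kept.
#' @return chimeric sequence (character) with a `provenance` attribute.
#' @export
make_chimera <- function(n_donor, c_acceptor, donor_boundary,
                         acceptor_boundary) {
  d <- as_seq_vector(n_donor)[[1]]
  a <- as_seq_vector(c_acceptor)[[1]]
  if (donor_boundary < 1 || donor_boundary > nchar(d))
    stop("donor_boundary out of range 1..", nchar(d))
  if (acceptor_boundary < 1 || acceptor_boundary > nchar(a))
    stop("acceptor_boundary out of range 1..", nchar(a))
  out <- paste0(substr(d, 1, donor_boundary),
                substr(a, acceptor_boundary, nchar(a)))
  attr(out, "provenance") <- sprintf(
    "N-terminus donor[1..%d] + acceptor[%d..%d]",
    donor_boundary, acceptor_boundary, nchar(a))
  out
}
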