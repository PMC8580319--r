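#' Specify a synthetic ACS-like protein family
#'
#' Describes a family of ~420-480-residue proteins with up to ten
#' ungapped planted motifs at controlled per-column conservation: the
#' nine ordered ACS motifs (the architecture genuine ACSs carry), an
#' AAT motif found only in aminotransferase-like controls, and the two
#' key residues (a glutamine inside motif 2, standing for the
#' cross-subunit Q98; an asparagine inside motif 5, standing for the
#' PLP-contacting N217).
#'
#' The family is homologous over the whole chain, as ACS-like proteins
#' are over the AAT fold: inter-motif regions descend from a family
#' scaffold with their own (lower) per-column conservation, and the
#' structurally distinct negative classes (`seven_only`, emulating a
#' lyase-like subfamily; `aat_control`, an aminotransferase-like one)
#' carry additionally diverged scaffolds, so subfamilies separate in a
#' tree the way the published one does. Point-mutant negatives keep the
#' family scaffold and deviate by exactly one residue.
#'
#' @param n_positive number of genuine-ACS sequences (default 50).
#' @param n_negative named integer vector of negative-class counts with
#'   names among `missing_motif`, `scrambled`, `q_mutant`, `n_mutant`,
#'   `seven_only`, `aat_control`.
#' @param conservation per-column probability `c` of the consensus
#'   letter in planted motifs (off-consensus letters are drawn from the
#'   background excluding the consensus, so the per-column consensus
#'   rate is exactly `c`). Key-residue columns are always planted.
#' @param spacer_conservation per-column probability of retaining the
#'   scaffold letter in inter-motif regions (default 0.5: linkers are
#'   conserved enough to carry the family's shared ancestry but much
#'   less than motif blocks; substituted letters are fresh background
#'   draws).
#' @param control_scaffold_retention fraction of family-scaffold letters
#'   retained in the diverged class scaffolds of `seven_only` and
#'   `aat_control` members (default 0.5).
#' @param motif_widths named widths of ACS1..ACS9 and AAT, each in
#'   `[6, 50]`.
#' @param length_range sequence length bounds (default 420-480).
#' @param spacer_mean geometric mean inter-motif spacer length
#'   (default 25); spacer lengths are drawn once per family.
#' @param background an `acs_background` (default uniform, the simplest
#'   null for p-value calibration).
#' @param q_offset,n_offset 1-based offsets of the key glutamine inside
#'   ACS2 and the key asparagine inside ACS5.
#' @return an object of class `acs_family_spec`.
#' @export
family_spec <- function(n_positive = 50,
                        n_negative = c(missing_motif = 10, scrambled = 10,
                                       q_mutant = 10, n_mutant = 10,
                                       seven_only = 5, aat_control = 5),
                        conservation = 0.9,
                        spacer_conservation = 0.5,
                        control_scaffold_retention = 0.5,
                        motif_widths = c(ACS1 = 15, ACS2 = 24, ACS3 = 12,
                                         ACS4 = 18, ACS5 = 16, ACS6 = 14,
                                         ACS7 = 21, ACS8 = 12, ACS9 = 17,
                                         AAT = 14),
                        length_range = c(420, 480), spacer_mean = 25,
                        background = uniform_background(),
                        q_offset = 10, n_offset = 8) {
  known <- c("missing_motif", "scrambled", "q_mutant", "n_mutant",
             "seven_only", "aat_control")
  if (!all(names(n_negative) %in% known))
    stop("unknown negative class: ",
         paste(setdiff(names(n_negative), known), collapse = ", "))
  if (any(n_negative < 0) || n_positive < 0) stop("counts must be >= 0")
  for (v in c(conservation, spacer_conservation,
              control_scaffold_retention))
    if (v < 0 || v > 1)
      stop("conservation parameters must lie in [0, 1]")
  stopifnot(all(paste0("ACS", 1:9) %in% names(motif_widths)))
  if (any(motif_widths < 6 | motif_widths > 50))
    stop("motif widths must lie in [6, 50]")
  if (q_offset > motif_widths[["ACS2"]] || n_offset > motif_widths[["ACS5"]])
    stop("key-residue offset outside its motif")
  if (sum(motif_widths[paste0("ACS", 1:9)]) > length_range[2])
    stop("planted motifs cannot fit the maximum sequence length")
  structure(list(n_positive = n_positive, n_negative = n_negative,
                 conservation = conservation,
                 spacer_conservation = spacer_conservation,
                 control_scaffold_retention = control_scaffold_retention,
                 motif_widths = motif_widths,
                 length_range = length_range, spacer_mean = spacer_mean,
                 background = as_background(background),
                 q_offset = q_offset, n_offset = n_offset),
            class = "acs_family_spec")
}

# sample one motif instance: consensus letter w.p. c, otherwise a
# background letter other than the consensus (renormalised); `fixed`
# columns always keep the consensus
sample_motif_instance <- function(consensus, c, bg, fixed = integer(0)) {
  idx <- encode_seq(consensus)
  w <- length(idx)
  out <- idx
  mutate <- stats::runif(w) >= c
  mutate[fixed] <- FALSE
  for (i in which(mutate)) {
    p <- bg
    p[idx[i]] <- 0
    out[i] <- sample.int(20, 1, prob = p)
  }
  decode_seq(out)
}

#' Sample a synthetic protein family with ground truth
#'
#' Generates the family described by a [family_spec()]: positives carry
#' ACS motifs 1-9 in order, non-overlapping, in a shared inter-motif
#' scaffold; each negative class deviates in its class-defining
#' feature (one missing motif, scrambled motif order, Q-to-A or N-to-A
#' key-residue mutation, a lyase-like member with only the seven
#' C-terminal motifs, or an aminotransferase-like control carrying the
#' AAT motif), the two structural control classes additionally carrying
#' subfamily-diverged scaffolds. Deterministic given `seed`.
#'
#' @param spec an `acs_family_spec`.
#' @param seed integer seed (required).
#' @param consensus optional named character vector of consensus strings
#'   (`ACS1`..`ACS9`, `AAT`) to reuse, e.g. to draw an independent
#'   family of the same protein family for training motif models; by
#'   default fresh consensus strings are drawn from the seed.
#' @return an object of class `acs_family`: list with `sequences`
#'   (named character), `truth` (data.frame: `sequence_id`, `class`,
#'   `is_positive`, `q_status`, `n_status`), `motif_positions`
#'   (data.frame: `sequence_id`, `motif_id`, `start`, `end`),
#'   `consensus` (named character incl. `AAT`), `reference` (list:
#'   `sequence`, `q_pos`, `n_pos`, `motif_starts`), `bg_tally` (counts
#'   of every letter drawn i.i.d. from the background during
#'   generation), and `spec`.
#' @export
sample_family <- function(spec, seed, consensus = NULL) {
  stopifnot(inherits(spec, "acs_family_spec"))
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  bg <- as.numeric(spec$background)
  widths <- spec$motif_widths
  acs_ids <- paste0("ACS", 1:9)
  tally <- integer(20)
  draw_bg <- function(n) {
    if (n <= 0) return(integer(0))
    idx <- sample.int(20, n, replace = TRUE, prob = bg)
    tally <<- tally + tabulate(idx, 20)
    idx
  }
  if (is.null(consensus)) {
    # per-seed random consensus strings, with the key residues planted
    consensus <- vapply(names(widths), function(id)
      decode_seq(draw_bg(widths[[id]])), character(1))
    substr(consensus[["ACS2"]], spec$q_offset, spec$q_offset) <- "Q"
    substr(consensus[["ACS5"]], spec$n_offset, spec$n_offset) <- "N"
  } else {
    stopifnot(all(names(widths) %in% names(consensus)),
              all(nchar(consensus[names(widths)]) == widths))
    consensus <- consensus[names(widths)]
  }
  cons_idx <- lapply(consensus, encode_seq)
  # family scaffold: junction segments S1 .. S10 around the nine slots
  w_acs <- unname(widths[acs_ids])
  # junction lengths: 5 + geometric, so motifs are individuated blocks
  # (mean spacer_mean overall)
  gmean <- max(spec$spacer_mean - 5, 1)
  for (try in 1:200) {
    jlen <- 5L + stats::rgeom(10, 1 / (gmean + 1))
    if (sum(w_acs) + sum(jlen) <= spec$length_range[2]) break
    if (try == 200) jlen <- rep(5L, 10)
  }
  scaffold <- lapply(jlen, draw_bg)
  L0 <- sum(w_acs) + sum(jlen)
  # subfamily scaffolds for the structural control classes: the
  # N-terminal region (through motif 2) is their own, the C-terminal
  # junctions descend from the family scaffold with extra divergence
  n_region_len <- jlen[1] + w_acs[1] + jlen[2] + w_acs[2]
  diverge <- function(idx, keep) {
    out <- idx
    sub <- stats::runif(length(idx)) >= keep
    out[sub] <- draw_bg(sum(sub))
    out
  }
  class_scaffold <- function(with_aat) {
    nt <- draw_bg(n_region_len)
    aat_at <- NA_integer_
    if (with_aat) {
      aat_at <- min(jlen[1] + 1L, n_region_len - widths[["AAT"]] + 1L)
      aat_at <- max(aat_at, 1L)
    }
    list(nterm = nt, aat_at = aat_at,
         junctions = lapply(scaffold[3:10], diverge,
                            keep = spec$control_scaffold_retention))
  }
  nneg <- function(cl) {
    v <- unname(spec$n_negative[cl])
    if (length(v) == 0 || is.na(v)) 0 else v
  }
  sc_seven <- if (nneg("seven_only") > 0) class_scaffold(FALSE) else NULL
  sc_aat <- if (nneg("aat_control") > 0) class_scaffold(TRUE) else NULL
  # per-sequence spacer divergence: letter substitutions plus light
  # indels (10% deletion, 10% insertion), so inter-motif regions are
  # homologous but not frame-locked across sequences
  mutate_spacer <- function(idx) {
    out <- diverge(idx, spec$spacer_conservation)
    if (!length(out)) return(out)
    out <- out[stats::runif(length(out)) >= 0.1]
    n_ins <- stats::rbinom(1, length(idx), 0.1)
    for (letter in draw_bg(n_ins)) {
      at <- sample.int(length(out) + 1L, 1) - 1L
      out <- append(out, letter, after = at)
    }
    out
  }
  classes <- c(rep("positive", spec$n_positive),
               rep(names(spec$n_negative), spec$n_negative))
  missing_k <- 0L
  make_one <- function(class) {
    mut_q <- class == "q_mutant"
    mut_n <- class == "n_mutant"
    sample_inst <- function(id) {
      fixed <- integer(0)
      if (id == "ACS2") fixed <- spec$q_offset
      if (id == "ACS5") fixed <- spec$n_offset
      s <- sample_motif_instance(consensus[[id]], spec$conservation, bg,
                                 fixed = fixed)
      if (id == "ACS2" && mut_q)
        substr(s, spec$q_offset, spec$q_offset) <- "A"
      if (id == "ACS5" && mut_n)
        substr(s, spec$n_offset, spec$n_offset) <- "A"
      s
    }
    blocks <- list()   # list of (kind, motif_id, letters)
    if (class %in% c("seven_only", "aat_control")) {
      sc <- if (class == "seven_only") sc_seven else sc_aat
      nt <- mutate_spacer(sc$nterm)
      if (class == "aat_control") {
        aat <- sample_motif_instance(consensus[["AAT"]],
                                     spec$conservation, bg)
        blocks <- c(blocks,
                    list(list(kind = "spacer",
                              letters = nt[seq_len(sc$aat_at - 1L)]),
                         list(kind = "motif", motif_id = "AAT",
                              letters = encode_seq(aat)),
                         list(kind = "spacer",
                              letters = {
                                from <- sc$aat_at + widths[["AAT"]]
                                if (from > length(nt)) integer(0)
                                else nt[from:length(nt)]
                              })))
      } else {
        blocks <- c(blocks, list(list(kind = "spacer", letters = nt)))
      }
      for (k in 3:9) {
        blocks <- c(blocks,
                    list(list(kind = "spacer",
                              letters = mutate_spacer(sc$junctions[[k - 2]])),
                         list(kind = "motif", motif_id = acs_ids[k],
                              letters = encode_seq(sample_inst(acs_ids[k])))))
      }
      blocks <- c(blocks,
                  list(list(kind = "spacer",
                            letters = mutate_spacer(sc$junctions[[8]]))))
    } else {
      slot_ids <- acs_ids
      if (class == "missing_motif") {
        missing_k <<- missing_k %% 9L + 1L
        slot_ids[missing_k] <- NA
      } else if (class == "scrambled") {
        slot_ids <- acs_ids[c(9, 2:8, 1)] # motif 9 before motif 1
      }
      for (k in 1:9) {
        blocks <- c(blocks,
                    list(list(kind = "spacer",
                              letters = mutate_spacer(scaffold[[k]]))))
        if (is.na(slot_ids[k])) {
          blocks <- c(blocks,
                      list(list(kind = "spacer",
                                letters = draw_bg(w_acs[k]))))
        } else {
          blocks <- c(blocks,
                      list(list(kind = "motif", motif_id = slot_ids[k],
                                letters = encode_seq(sample_inst(slot_ids[k])))))
        }
      }
      blocks <- c(blocks,
                  list(list(kind = "spacer",
                            letters = mutate_spacer(scaffold[[10]]))))
    }
    core_len <- sum(vapply(blocks, function(b) length(b$letters),
                           integer(1)))
    lo <- max(core_len, spec$length_range[1])
    hi <- max(core_len, spec$length_range[2])
    target <- lo + sample.int(hi - lo + 1L, 1) - 1L
    pad <- target - core_len
    n_pad <- if (pad > 0) sample.int(pad + 1L, 1) - 1L else 0L
    letters <- c(draw_bg(n_pad),
                 unlist(lapply(blocks, `[[`, "letters")),
                 draw_bg(pad - n_pad))
    pos <- n_pad + 1L
    rows <- list()
    for (b in blocks) {
      if (b$kind == "motif")
        rows[[length(rows) + 1]] <- data.frame(
          motif_id = b$motif_id, start = pos,
          end = pos + length(b$letters) - 1L)
      pos <- pos + length(b$letters)
    }
    q_status <- if (class %in% c("seven_only", "aat_control")) "absent"
      else if (class == "missing_motif" && missing_k == 2L) "absent"
      else if (mut_q) "mutant" else "present"
    n_status <- if (class == "missing_motif" && missing_k == 5L) "absent"
      else if (mut_n) "mutant" else "present"
    list(seq = decode_seq(letters), positions = do.call(rbind, rows),
         q_status = q_status, n_status = n_status)
  }
  ids <- sprintf("%s_%03d", ifelse(classes == "positive", "POS", "NEG"),
                 seq_along(classes))
  seqs <- character(length(classes))
  truth_rows <- list(); pos_rows <- list()
  for (i in seq_along(classes)) {
    one <- make_one(classes[i])
    seqs[i] <- one$seq
    truth_rows[[i]] <- data.frame(sequence_id = ids[i], class = classes[i],
                                  is_positive = classes[i] == "positive",
                                  q_status = one$q_status,
                                  n_status = one$n_status)
    pr <- one$positions
    if (!is.null(pr)) {
      pr$sequence_id <- ids[i]
      pos_rows[[i]] <- pr[, c("sequence_id", "motif_id", "start", "end")]
    }
  }
  names(seqs) <- ids
  # reference: the family scaffold with consensus motifs, padded to the
  # minimum length; deterministic per seed
  set.seed(seed + 1000003L)
  ref_letters <- integer(0)
  ref_starts <- stats::setNames(integer(9), acs_ids)
  for (k in 1:9) {
    ref_letters <- c(ref_letters, scaffold[[k]])
    ref_starts[k] <- length(ref_letters) + 1L
    ref_letters <- c(ref_letters, cons_idx[[acs_ids[k]]])
  }
  ref_letters <- c(ref_letters, scaffold[[10]])
  pad <- max(0L, spec$length_range[1] - length(ref_letters))
  ref_letters <- c(ref_letters,
                   sample.int(20, pad, replace = TRUE, prob = bg))
  reference <- list(sequence = decode_seq(ref_letters),
                    q_pos = ref_starts[["ACS2"]] + spec$q_offset - 1L,
                    n_pos = ref_starts[["ACS5"]] + spec$n_offset - 1L,
                    motif_starts = ref_starts)
  structure(list(sequences = seqs,
                 truth = do.call(rbind, truth_rows),
                 motif_positions = do.call(rbind, pos_rows),
                 consensus = consensus, reference = reference,
                 bg_tally = stats::setNames(tally, AA_LETTERS),
                 spec = spec, seed = seed),
            class = "acs_family")
}

#' @export
print.acs_family <- function(x, ...) {
  cat(sprintf(
    "Synthetic ACS-like family: %d sequences (%d positive), c = %.2f, seed %s\n",
    length(x$sequences), sum(x$truth$is_positive),
    x$spec$conservation, format(x$seed)))
  invisible(x)
}

#' Build motif models from a family's planted instances
#'
#' Extracts the ground-truth instances of each planted motif and builds
#' `acs_motif` models, emulating a motif library derived from a training
#' family (the role a published motif table plays for real data).
#'
#' @param family an `acs_family`.
#' @param pseudocount passed to [build_motif_model()].
#' @return named list of `acs_motif` (ACS1..ACS9 and, when the family
#'   contains AAT-control members, AAT).
#' @export
family_motifs <- function(family, pseudocount = 0.375) {
  mp <- family$motif_positions
  out <- list()
  for (id in intersect(c(paste0("ACS", 1:9), "AAT"), unique(mp$motif_id))) {
    rows <- mp[mp$motif_id == id, , drop = FALSE]
    # exclude mutated key-residue instances so models reflect the motif
    if (id %in% c("ACS2", "ACS5")) {
      cls <- family$truth$class[match(rows$sequence_id,
                                      family$truth$sequence_id)]
      drop <- (id == "ACS2" & cls == "q_mutant") |
              (id == "ACS5" & cls == "n_mutant")
      rows <- rows[!drop, , drop = FALSE]
    }
    inst <- substring(family$sequences[rows$sequence_id], rows$start,
                      rows$end)
    out[[id]] <- build_motif_model(inst, family$spec$background,
                                   pseudocount = pseudocount,
                                   motif_id = id)
  }
  out
}

#' Calibration checks of the generator's output
#'
#' Chi-squared goodness of fit of the generator's background letter
#' draws (scaffold letters, substitutions, padding — every letter drawn
#' i.i.d. from the declared background, tallied during generation)
#' against that background, and a binomial estimate of the realised
#' per-column motif conservation (key-residue columns excluded).
#'
#' @param family an `acs_family`.
#' @return list with `n_background_letters`, `chisq_p`,
#'   `conservation_hat`, `conservation_se`, `n_motif_columns`, `note`.
#' @export
empirical_composition_check <- function(family) {
  bg <- as.numeric(family$spec$background)
  tally <- family$bg_tally
  note <- character(0)
  chisq_p <- NA_real_
  if (sum(tally) == 0) {
    note <- "no background letters generated: composition untestable"
  } else {
    chisq_p <- stats::chisq.test(tally, p = bg)$p.value
  }
  seqs <- family$sequences
  mp <- family$motif_positions
  match_flags <- logical(0)
  for (i in seq_len(nrow(mp))) {
    id <- mp$sequence_id[i]
    mid <- mp$motif_id[i]
    cons <- family$consensus[[mid]]
    inst <- substr(seqs[[id]], mp$start[i], mp$end[i])
    skip <- integer(0)
    if (mid == "ACS2") skip <- family$spec$q_offset
    if (mid == "ACS5") skip <- family$spec$n_offset
    cols <- setdiff(seq_len(nchar(cons)), skip)
    match_flags <- c(match_flags,
                     strsplit(inst, "")[[1]][cols] ==
                       strsplit(cons, "")[[1]][cols])
  }
  list(n_background_letters = sum(tally), chisq_p = chisq_p,
       conservation_hat = mean(match_flags),
       conservation_se = stats::sd(match_flags) /
         sqrt(length(match_flags)),
       n_motif_columns = length(match_flags),
       note = if (length(note)) note else "ok")
}

#' Perturb coordinates to a known post-superposition RMSD
#'
#' Adds a random displacement field orthogonalised against the six
#' rigid-body modes of the base configuration (three translations,
#' three infinitesimal rotations) and rescaled so that the RMSD after
#' optimal rigid superposition equals `target_rmsd` within 1e-9
#' (verified internally by running [kabsch_superpose()]).
#'
#' @param xyz n x 3 base coordinates (n >= 4, non-collinear).
#' @param target_rmsd desired post-superposition RMSD (Angstrom).
#' @param seed integer seed.
#' @return perturbed n x 3 matrix.
#' @export
perturb_coordinates <- function(xyz, target_rmsd, seed) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(ncol(xyz) == 3)
  if (n < 4) stop("need at least 4 points")
  if (target_rmsd < 0) stop("target rmsd must be >= 0")
  if (target_rmsd == 0) return(xyz)
  set.seed(seed)
  D <- matrix(stats::rnorm(n * 3), ncol = 3)
  ctr <- sweep(xyz, 2, colMeans(xyz))
  # rigid-body modes as columns of a (3n x 6) basis
  basis <- matrix(0, nrow = 3 * n, ncol = 6)
  for (k in 1:3) basis[seq(k, 3 * n, by = 3), k] <- 1
  rots <- list(cbind(0 * ctr[, 1], -ctr[, 3], ctr[, 2]),
               cbind(ctr[, 3], 0 * ctr[, 1], -ctr[, 1]),
               cbind(-ctr[, 2], ctr[, 1], 0 * ctr[, 1]))
  for (k in 1:3) basis[, 3 + k] <- as.numeric(t(rots[[k]]))
  Q <- qr.Q(qr(basis))
  d <- as.numeric(t(D))
  d <- d - Q %*% crossprod(Q, d)
  D <- matrix(d, ncol = 3, byrow = TRUE)
  if (sqrt(mean(rowSums(D^2))) < 1e-12)
    stop("degenerate displacement field")
  measure <- function(s) kabsch_superpose(xyz, xyz + s * D)$rmsd
  f <- function(s) measure(s) - target_rmsd
  s0 <- target_rmsd / sqrt(mean(rowSums(D^2)))
  root <- if (abs(f(s0)) < 1e-12) s0 else {
    lo <- s0; hi <- s0; it <- 0L
    while (f(hi) < 0 && it < 200L) { hi <- hi * 2; it <- it + 1L }
    it <- 0L
    while (f(lo) > 0 && it < 200L) { lo <- lo / 2; it <- it + 1L }
    if (lo >= hi) { lo <- lo * (1 - 1e-6); hi <- hi * (1 + 1e-6) }
    stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
  }
  out <- xyz + root * D
  achieved <- kabsch_superpose(xyz, out)$rmsd
  if (abs(achieved - target_rmsd) > 1e-9)
    stop("perturbation target missed: ", achieved)
  out
}

#' A smooth synthetic protein-like CA trace
#'
#' Helical-ish random walk used as a base configuration for structural
#' fixtures; deterministic given `seed`.
#'
#' @param n number of points.
#' @param seed integer seed.
#' @return n x 3 matrix (Angstrom scale).
#' @export
synthetic_ca_trace <- function(n = 400, seed = 1) {
  set.seed(seed)
  t <- seq_len(n)
  base <- cbind(2.3 * cos(t / 1.75), 2.3 * sin(t / 1.75), 1.5 * t)
  drift <- apply(matrix(stats::rnorm(n * 3, sd = 0.4), ncol = 3), 2,
                 cumsum)
  base + drift
}
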