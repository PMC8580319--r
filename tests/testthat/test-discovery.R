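# Planted-motif fixtures: random background sequences with one exact (or
# conservation-degraded) copy of a consensus at a random position.
plant_sequences <- function(consensus, n_seq, len, seed) {
  set.seed(seed)
  letters20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  w <- nchar(consensus)
  sapply(seq_len(n_seq), function(i) {
    s <- paste(sample(letters20, len, TRUE), collapse = "")
    pos <- sample.int(len - w + 1, 1)
    substr(s, pos, pos + w - 1) <- consensus
    s
  })
}

test_that("an exactly planted 8-mer is recovered with all its sites", {
  seqs <- plant_sequences("WWCHYKQW", 10, 80, seed = 101)
  motifs <- discover_motifs(seqs, widths = 8, max_motifs = 1,
                            n_restarts = 5, seed = 1)
  expect_length(motifs, 1)
  expect_equal(motifs[[1]]$consensus, "WWCHYKQW")
  expect_equal(motifs[[1]]$nsites, 10)
})

test_that("discovery is byte-identical under the same seed", {
  seqs <- plant_sequences("WWCHYKQW", 8, 70, seed = 102)
  m1 <- discover_motifs(seqs, widths = c(6, 8), max_motifs = 2,
                        n_restarts = 4, seed = 7)
  m2 <- discover_motifs(seqs, widths = c(6, 8), max_motifs = 2,
                        n_restarts = 4, seed = 7)
  expect_identical(m1, m2)
})

test_that("planted consensus is recovered at every discovery-bound width", {
  set.seed(55)
  letters20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  for (w in c(6, 12, 25, 50)) {
    cons <- paste(sample(letters20, w, TRUE), collapse = "")
    seqs <- plant_sequences(cons, 10, 140, seed = 200 + w)
    motifs <- discover_motifs(seqs, widths = w, max_motifs = 1,
                              n_restarts = 5, seed = 3)
    expect_length(motifs, 1)
    expect_equal(motifs[[1]]$consensus, cons, info = paste("width", w))
  }
})

test_that("erased occurrences are not rediscovered", {
  seqs <- plant_sequences("WWCHYKQWHHMM", 10, 90, seed = 103)
  motifs <- discover_motifs(seqs, widths = 12, max_motifs = 3,
                            n_restarts = 5, seed = 9)
  expect_gte(length(motifs), 1)
  if (length(motifs) >= 2) {
    s1 <- motifs[[1]]$sites
    for (k in 2:length(motifs)) {
      sk <- motifs[[k]]$sites
      shared <- merge(s1, sk, by = "sequence_id")
      if (nrow(shared) == 0) next
      ov <- pmax(0, pmin(shared$start.x + 11, shared$start.y + 11) -
                   pmax(shared$start.x, shared$start.y) + 1)
      expect_true(all(ov / 12 <= 0.5))
    }
  }
})

test_that("degenerate single-letter input yields no motif", {
  seqs <- rep(paste(rep("A", 60), collapse = ""), 5)
  motifs <- discover_motifs(seqs, widths = c(6, 8), max_motifs = 3,
                            n_restarts = 3, seed = 2)
  expect_length(motifs, 0)
})

test_that("discovery separates shared ACS motifs from control-only content", {
  # genuine members carry all nine motifs; aminotransferase-like controls
  # carry the AAT motif plus only the seven C-terminal ones
  spec <- family_spec(n_positive = 8,
                      n_negative = c(aat_control = 4),
                      conservation = 1.0)
  fam <- sample_family(spec, seed = 31)
  widths <- sort(unique(unname(spec$motif_widths)))
  motifs <- discover_motifs(fam$sequences, widths = widths,
                            max_motifs = 15, n_restarts = 4, seed = 5)
  expect_gte(length(motifs), 9)
  genuine <- fam$truth$sequence_id[fam$truth$is_positive]
  controls <- fam$truth$sequence_id[!fam$truth$is_positive]
  mp <- fam$motif_positions
  # match each planted motif to the discovered motif overlapping its
  # ground-truth instances
  covered_by <- function(m, planted_id) {
    truth <- mp[mp$motif_id == planted_id, ]
    hit <- merge(m$sites, truth, by = "sequence_id")
    if (nrow(hit) == 0) return(character(0))
    ov <- pmax(0, pmin(hit$start.x + m$width - 1, hit$end) -
                 pmax(hit$start.x, hit$start.y) + 1)
    hit$sequence_id[ov >= 0.5 * pmin(m$width, hit$end - hit$start.y + 1)]
  }
  match_of <- function(planted_id) {
    cov <- lapply(motifs, covered_by, planted_id = planted_id)
    motifs[[which.max(lengths(cov))]]
  }
  for (id in paste0("ACS", 1:9)) {
    m <- match_of(id)
    expect_setequal(intersect(covered_by(m, id),
                              mp$sequence_id[mp$motif_id == id]),
                    mp$sequence_id[mp$motif_id == id])
  }
  # the two N-terminal motifs are found only in genuine members
  for (id in c("ACS1", "ACS2"))
    expect_true(all(match_of(id)$sites$sequence_id %in% genuine))
  # the AAT-like content is found and stays out of the genuine set
  aat <- match_of("AAT")
  expect_setequal(covered_by(aat, "AAT"), controls)
  expect_true(all(aat$sites$sequence_id %in% controls))
})
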