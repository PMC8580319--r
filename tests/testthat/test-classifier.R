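# A conservation-1.0 family provides exact fixtures; motifs are built
# from the planted instances and classification runs against the
# family's own reference.
cls_family <- function(seed = 42)
  sample_family(family_spec(
    n_positive = 6,
    n_negative = c(missing_motif = 2, scrambled = 1, q_mutant = 1,
                   n_mutant = 1, seven_only = 1, aat_control = 1),
    conservation = 1.0), seed = seed)

fam <- cls_family()
motifs <- family_motifs(fam)
ref <- fam$reference
req <- stats::setNames(c("Q", "N"), c(ref$q_pos, ref$n_pos))

test_that("each negative class flips exactly its own conjunct", {
  batch <- classify_batch(fam$sequences, motifs, ref$sequence,
                          requirements = req)
  expect_equal(classification_accuracy(batch, fam$truth), 1.0)
  tr <- fam$truth[match(batch$sequence_id, fam$truth$sequence_id), ]
  expect_true(all(batch$predicted_acs[tr$class == "positive"]))
  m <- as.matrix(batch[, paste0("ACS", 1:9)])
  for (i in seq_len(nrow(batch))) {
    cl <- tr$class[i]
    if (cl == "positive") expect_true(all(m[i, ]))
    if (cl == "missing_motif") expect_equal(sum(m[i, ]), 8)
    if (cl == "scrambled") {
      expect_true(all(m[i, ]))
      expect_false(batch$ordered[i])
    }
    if (cl == "q_mutant") expect_equal(batch$Q98[i], "A")
    if (cl == "n_mutant") expect_equal(batch$N217[i], "A")
    if (cl == "seven_only") expect_false(any(m[i, 1:2]))
    if (cl == "aat_control") expect_true(batch$AAT[i])
  }
  # the motif-complete N-mutant carries the inactive-outlier note
  nmut <- which(tr$class == "n_mutant")
  expect_match(batch$notes[nmut], "asparagine")
})

test_that("single-conjunct ablations of a passing sequence flip it", {
  pos_id <- fam$truth$sequence_id[fam$truth$class == "positive"][1]
  s <- fam$sequences[[pos_id]]
  mp <- fam$motif_positions[fam$motif_positions$sequence_id == pos_id, ]
  cls <- function(x) classify_sequence(x, motifs, ref$sequence, req)
  expect_true(cls(s)$predicted_acs)
  # delete motif 5 by replacing its block with a neutral letter run
  r5 <- mp[mp$motif_id == "ACS5", ]
  ablated <- s
  substr(ablated, r5$start, r5$end) <-
    paste(rep("G", r5$end - r5$start + 1), collapse = "")
  expect_false(cls(ablated)$predicted_acs)
  # mutate the key glutamine inside motif 2
  r2 <- mp[mp$motif_id == "ACS2", ]
  qpos <- r2$start + fam$spec$q_offset - 1
  qmut <- s
  substr(qmut, qpos, qpos) <- "A"
  expect_false(cls(qmut)$predicted_acs)
  # mutate the key asparagine inside motif 5
  npos <- r5$start + fam$spec$n_offset - 1
  nmut <- s
  substr(nmut, npos, npos) <- "A"
  out <- cls(nmut)
  expect_false(out$predicted_acs)
  expect_true(any(grepl("asparagine", out$exception_notes)))
})

test_that("the N-terminal chimera restores a seven-motif backbone", {
  donor_id <- fam$truth$sequence_id[fam$truth$class == "positive"][1]
  acceptor_id <- fam$truth$sequence_id[fam$truth$class == "seven_only"]
  donor <- fam$sequences[[donor_id]]
  acceptor <- fam$sequences[[acceptor_id]]
  mp <- fam$motif_positions
  cls <- function(x) classify_sequence(x, motifs, ref$sequence, req)
  expect_false(cls(acceptor)$predicted_acs)
  donor_boundary <- mp$end[mp$sequence_id == donor_id &
                             mp$motif_id == "ACS2"]
  acceptor_boundary <- mp$start[mp$sequence_id == acceptor_id &
                                  mp$motif_id == "ACS3"] - 1
  chim <- make_chimera(donor, acceptor, donor_boundary,
                       acceptor_boundary)
  expect_true(cls(chim)$predicted_acs)
  # the reverse swap: replacing the motif-2 region of a passing sequence
  # with motif-free residues abolishes the prediction
  r2 <- mp[mp$sequence_id == donor_id & mp$motif_id == "ACS2", ]
  swapped <- donor
  substr(swapped, r2$start, r2$end) <-
    paste(rep("S", r2$end - r2$start + 1), collapse = "")
  expect_false(cls(swapped)$predicted_acs)
})

test_that("relaxing the asparagine conjunct restores the two-level reading", {
  nmut_id <- fam$truth$sequence_id[fam$truth$class == "n_mutant"]
  strict <- classify_sequence(fam$sequences[[nmut_id]], motifs,
                              ref$sequence, req)
  lax <- classify_sequence(fam$sequences[[nmut_id]], motifs,
                           ref$sequence, req,
                           config = acs_config(strict_n217 = FALSE))
  expect_false(strict$predicted_acs)
  expect_true(lax$predicted_acs)
})

test_that("batch interface enforces its contracts", {
  expect_error(classify_batch(fam$sequences, motifs[-2], ref$sequence,
                              requirements = req), "ACS2")
  dup <- fam$sequences[c(1, 1)]
  expect_error(classify_batch(dup, motifs, ref$sequence,
                              requirements = req), "duplicate")
  expect_warning(empty <- classify_batch(character(0), motifs,
                                         ref$sequence,
                                         requirements = req), "empty")
  expect_equal(nrow(empty), 0)
  batch <- classify_batch(fam$sequences[1:3], motifs, ref$sequence,
                          requirements = req)
  tab <- evidence_table(batch)
  expect_equal(tab$predicted_ACS, ifelse(batch$predicted_acs, "+", "-"))
  expect_true(all(unlist(tab[, paste0("ACS", 1:9)]) %in% c("+", "-")))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_evidence(batch, tsv, js)
  expect_equal(nrow(utils::read.delim(tsv)), 3)
  expect_named(jsonlite::read_json(js), batch$sequence_id)
})

test_that("config hashes are stable and parameter-sensitive", {
  expect_identical(acs_config()$hash, acs_config()$hash)
  expect_false(identical(acs_config()$hash,
                         acs_config(p_threshold = 1e-5)$hash))
})

test_that("exactly one row is positive in the constructed four-way batch", {
  ids <- vapply(c("positive", "missing_motif", "q_mutant", "n_mutant"),
                function(cl) fam$truth$sequence_id[fam$truth$class == cl][1],
                character(1))
  batch <- classify_batch(fam$sequences[ids], motifs, ref$sequence,
                          requirements = req)
  expect_equal(sum(batch$predicted_acs), 1L)
  expect_true(batch$predicted_acs[1])
})
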