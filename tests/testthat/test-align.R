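test_that("self-alignment has no gaps and the diagonal self-score", {
  s <- "MKTAYIAKQRQISFVK"
  aln <- global_align(s, s)
  expect_equal(aln$aligned_query, s)
  expect_equal(aln$aligned_reference, s)
  B <- substitution_matrix("BLOSUM62")
  ch <- strsplit(s, "")[[1]]
  expect_equal(aln$score, sum(B[cbind(ch, ch)]))
})

test_that("alignment scores equal the memoised-recursion oracle", {
  B <- substitution_matrix("BLOSUM62")
  expect_equal(global_align("HEAGAWGHEE", "PAWHEAE")$score,
               oracle_global_score("HEAGAWGHEE", "PAWHEAE", B, 11, 1))
  set.seed(19)
  letters20 <- colnames(B)[1:20]
  for (k in 1:20) {
    a <- paste(sample(letters20, sample(3:12, 1), TRUE), collapse = "")
    b <- paste(sample(letters20, sample(3:12, 1), TRUE), collapse = "")
    expect_equal(global_align(a, b)$score,
                 oracle_global_score(a, b, B, 11, 1),
                 info = paste(a, b))
  }
})

test_that("alignment agrees with an independent implementation", {
  B <- substitution_matrix("BLOSUM62")
  set.seed(23)
  letters20 <- colnames(B)[1:20]
  for (k in 1:10) {
    a <- paste(sample(letters20, sample(20:60, 1), TRUE), collapse = "")
    b <- paste(sample(letters20, sample(20:60, 1), TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = "BLOSUM62",
                                         gapOpening = 11, gapExtension = 1,
                                         type = "global", scoreOnly = TRUE)
    expect_equal(global_align(a, b)$score, ref)
  }
})

test_that("alignment is symmetric and recovers the inputs", {
  a <- "WWCHYKQWACDEFGHIKL"
  b <- "WWCHYKACDEFGHL"
  f <- global_align(a, b)
  r <- global_align(b, a)
  expect_equal(f$score, r$score)
  expect_equal(f$aligned_query, r$aligned_reference)
  expect_equal(f$aligned_reference, r$aligned_query)
  expect_equal(gsub("-", "", f$aligned_query), a)
  expect_equal(gsub("-", "", f$aligned_reference), b)
  expect_false(any(strsplit(f$aligned_query, "")[[1]] == "-" &
                     strsplit(f$aligned_reference, "")[[1]] == "-"))
  expect_error(global_align("", a), "empty")
})

test_that("reference positions map through alignments", {
  ref <- synthetic_reference()
  aln <- global_align(ref$sequence, ref$sequence)
  m98 <- map_reference_position(aln, 98)
  expect_equal(m98$query_residue, "Q")
  expect_equal(m98$query_position, 98L)
  m217 <- map_reference_position(aln, 217)
  expect_equal(m217$query_residue, "N")
  expect_error(map_reference_position(aln, 0), "out of range")
  expect_error(map_reference_position(aln, 10000), "out of range")

  # deleting 90..110 sends position 98 to "deleted"
  del <- paste0(substr(ref$sequence, 1, 89),
                substr(ref$sequence, 111, nchar(ref$sequence)))
  a2 <- global_align(del, ref$sequence)
  m <- map_reference_position(a2, 98)
  expect_true(is.na(m$query_residue))
})

test_that("mapping is bijective on non-gap columns", {
  ref <- synthetic_reference()
  q <- paste0(substr(ref$sequence, 1, 150),
              substr(ref$sequence, 181, nchar(ref$sequence)))
  fwd <- global_align(q, ref$sequence)
  rev <- global_align(ref$sequence, q)
  n_ref <- nchar(ref$sequence)
  for (p in seq(1, n_ref, by = 23)) {
    m <- map_reference_position(fwd, p)
    if (is.na(m$query_position)) next
    back <- map_reference_position(rev, m$query_position)
    expect_equal(back$query_position, p)
  }
})

test_that("key-residue statuses follow the construction", {
  ref <- synthetic_reference()$sequence
  kr <- check_key_residues(ref, ref)
  expect_equal(kr$status, c("match", "match"))

  q98a <- ref
  substr(q98a, 98, 98) <- "A"
  kr2 <- check_key_residues(q98a, ref)
  expect_equal(kr2$status, c("mismatch", "match"))
  expect_equal(kr2$query_letter[1], "A")

  n217a <- ref
  substr(n217a, 217, 217) <- "A"
  kr3 <- check_key_residues(n217a, ref)
  expect_equal(kr3$status, c("match", "mismatch"))
})

test_that("chimeras concatenate with conserved length and provenance", {
  s <- synthetic_reference()$sequence
  ident <- make_chimera(s, s, 120, 121)
  expect_equal(as.character(ident), s)
  a <- substr(s, 1, 200); b <- substr(s, 1, 300)
  ch <- make_chimera(a, b, 150, 40)
  expect_equal(nchar(ch), 150 + (300 - 40 + 1))
  expect_match(attr(ch, "provenance"), "donor")
  expect_error(make_chimera(a, b, 0, 10), "out of range")
  expect_error(make_chimera(a, b, 10, 999), "out of range")
})
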