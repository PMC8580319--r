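test_that("progressive MSA handles identical and pairwise inputs", {
  seqs <- c(a = "MKTAYIAKQR", b = "MKTAYIAKQR", c = "MKTAYIAKQR")
  msa <- progressive_msa(seqs)
  expect_false(any(grepl("-", msa$rows)))
  expect_equal(unname(msa$rows), unname(seqs))

  two <- c(x = "HEAGAWGHEE", y = "PAWHEAE")
  msa2 <- progressive_msa(two)
  aln <- global_align(two[["x"]], two[["y"]])
  expect_equal(unname(msa2$rows[["x"]]), aln$aligned_query)
  expect_equal(unname(msa2$rows[["y"]]), aln$aligned_reference)
})

test_that("MSA rows degap to the input sequences", {
  set.seed(41)
  letters20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  base <- paste(sample(letters20, 60, TRUE), collapse = "")
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    at <- sample(seq_along(ch), k)
    ch[at] <- sample(letters20, k, TRUE)
    paste(ch, collapse = "")
  }
  seqs <- c(a = base, b = mut(base, 6), c = mut(base, 10),
            d = substr(base, 10, 60))
  msa <- progressive_msa(seqs)
  expect_equal(length(unique(nchar(msa$rows))), 1L)
  for (id in names(seqs))
    expect_equal(gsub("-", "", msa$rows[[id]]), unname(seqs[[id]]))
  # the truncated member is aligned with terminal gaps
  expect_match(msa$rows[["d"]], "^-+")
})

test_that("distances follow the p and Poisson closed forms", {
  rows <- c(r1 = "AAAA", r2 = "AAAT")
  Dp <- distance_matrix(structure(list(rows = rows), class = "acs_msa"),
                        model = "p")
  expect_equal(Dp["r1", "r2"], 0.25)
  Dpois <- distance_matrix(structure(list(rows = rows), class = "acs_msa"))
  expect_equal(Dpois["r1", "r2"], -log(0.75), tolerance = 1e-12)
  expect_equal(diag(Dpois), c(r1 = 0, r2 = 0))

  same <- c(r1 = "ACDE", r2 = "ACDE")
  expect_equal(max(distance_matrix(
    structure(list(rows = same), class = "acs_msa"))), 0)

  sat <- c(r1 = "AAAA", r2 = "TTTT")
  expect_error(distance_matrix(
    structure(list(rows = sat), class = "acs_msa")), "saturated")
  nocol <- c(r1 = "AA--", r2 = "--TT")
  expect_error(distance_matrix(
    structure(list(rows = nocol), class = "acs_msa")),
    "no comparable columns")
})

test_that("three-taxon NJ matches the closed form", {
  D <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- neighbor_joining(D)
  pl <- cophenetic(tree)
  expect_equal(pl[rownames(D), colnames(D)], D, tolerance = 1e-12)
  # branch lengths: a = (dab + dac - dbc)/2 etc.
  la <- tree$edge.length[tree$edge[, 2] == which(tree$tip.label == "a")]
  expect_equal(la, (3 + 4 - 5) / 2)
})

test_that("NJ recovers additive matrices exactly (consistency)", {
  for (seed in 1:20) {
    n <- sample(4:6, 1)
    gen <- random_additive_matrix(n, seed)
    tree <- neighbor_joining(gen$D)
    pl <- cophenetic(tree)[rownames(gen$D), colnames(gen$D)]
    expect_lt(max(abs(pl - gen$D)), 1e-9)
    expect_true(all(ape::prop.part(tree, check.labels = FALSE) %in%
                      ape::prop.part(gen$tree, check.labels = FALSE)) ||
                  ape::dist.topo(ape::unroot(tree),
                                 ape::unroot(gen$tree)) == 0)
  }
})

test_that("matrix validation rejects malformed inputs", {
  D <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(neighbor_joining(D), "at least 3")
  D3 <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(D3), "symmetric")
})

test_that("bootstrap supports behave at the extremes", {
  rows <- c(A1 = "AAAAAAAAAA", A2 = "AAAAAAAAAA",
            B1 = "AATTTTTTAA", B2 = "AATTTTTTAA")
  msa <- structure(list(ids = names(rows), rows = rows),
                   class = "acs_msa")
  tree <- bootstrap_support(msa, n_replicates = 50, seed = 4)
  sup <- attr(tree, "support")
  expect_equal(nrow(sup), 1L)
  expect_equal(sup$support, 100)

  one <- bootstrap_support(msa, n_replicates = 1, seed = 9)
  expect_true(all(attr(one, "support")$support %in% c(0, 100)))
})

test_that("replicate seeds are counter-based and order-independent", {
  set.seed(123)
  letters4 <- c("A", "C", "G", "T")
  rows <- vapply(1:5, function(i)
    paste(sample(letters4, 40, TRUE), collapse = ""), character(1))
  names(rows) <- paste0("t", 1:5)
  msa <- structure(list(ids = names(rows), rows = rows),
                   class = "acs_msa")
  t1 <- bootstrap_support(msa, n_replicates = 20, model = "p", seed = 77)
  t2 <- bootstrap_support(msa, n_replicates = 20, model = "p", seed = 77)
  expect_identical(attr(t1, "support"), attr(t2, "support"))
})

test_that("monophyly matches edge-bipartition enumeration and ape", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,(e:1,f:1):1);")
  expect_true(is_monophyletic(tree, c("a", "b")))
  expect_true(is_monophyletic(tree, c("c", "d")))
  expect_false(is_monophyletic(tree, c("a", "c")))
  expect_false(is_monophyletic(tree, c("a", "b", "c")))
  expect_true(is_monophyletic(tree, c("c", "d", "e", "f")))
  expect_true(is_monophyletic(tree, "a"))
  expect_true(is_monophyletic(tree, tree$tip.label))
  expect_error(is_monophyletic(tree, "zz"), "unknown")

  # randomised cross-check against the independent implementation
  for (seed in 1:10) {
    set.seed(seed)
    rt <- ape::rtree(7, rooted = FALSE)
    subset <- sample(rt$tip.label, sample(2:5, 1))
    expect_equal(is_monophyletic(rt, subset),
                 ape::is.monophyletic(rt, subset))
  }
})
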