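#' Progressive multiple sequence alignment
#'
#' A simple, deterministic progressive aligner: pairwise global
#' alignments give fractional-identity distances, a UPGMA guide tree
#' orders the merges, and profiles are aligned profile-to-profile with
#' affine gaps using sum-of-pairs substitution scores. A declared,
#' documented stand-in for production aligners; downstream tree claims
#' are validated as topological properties.
#'
#' @param sequences named character vector (>= 1 sequence).
#' @param matrix substitution matrix name or matrix (default BLOSUM62).
#' @param gap_open,gap_extend affine gap parameters (defaults 11, 1).
#' @return object of class `acs_msa`: list with `ids` and `rows`
#'   (named, equal-length gapped strings).
#' @export
progressive_msa <- function(sequences, matrix = "BLOSUM62",
                            gap_open = 11, gap_extend = 1) {
  seqs <- as_seq_vector(sequences)
  n <- length(seqs)
  if (n == 0) stop("no sequences")
  if (is.character(matrix) && length(matrix) == 1)
    matrix <- substitution_matrix(matrix)
  if (n == 1)
    return(structure(list(ids = names(seqs), rows = seqs),
                     class = "acs_msa"))
  M20 <- matrix[AA_LETTERS, AA_LETTERS]
  prof_counts <- function(rows) {
    # 20 x L letter frequencies of an aligned block (gaps weight 0)
    L <- nchar(rows[1])
    chs <- do.call(rbind, strsplit(rows, ""))
    f <- matrix(0, nrow = 20, ncol = L)
    for (a in seq_len(20)) f[a, ] <- colSums(chs == AA_LETTERS[a])
    f / length(rows)
  }
  align_profiles <- function(rowsA, rowsB) {
    S <- t(prof_counts(rowsA)) %*% M20 %*% prof_counts(rowsB)
    path <- cpp_profile_align(S, gap_open, gap_extend)
    expand <- function(rows, idx) {
      chs <- do.call(rbind, strsplit(rows, ""))
      out <- matrix("-", nrow = nrow(chs), ncol = length(idx))
      out[, idx > 0] <- chs[, idx[idx > 0], drop = FALSE]
      apply(out, 1, paste, collapse = "")
    }
    c(expand(rowsA, path$a), expand(rowsB, path$b))
  }
  # guide tree from pairwise identity distances
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    aln <- global_align(seqs[[i]], seqs[[j]], matrix = matrix,
                        gap_open = gap_open, gap_extend = gap_extend)
    qa <- strsplit(aln$aligned_query, "")[[1]]
    ra <- strsplit(aln$aligned_reference, "")[[1]]
    both <- qa != "-" & ra != "-"
    id <- if (any(both)) mean(qa[both] == ra[both]) else 0
    D[i, j] <- D[j, i] <- 1 - id
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  merged_rows <- vector("list", nrow(hc$merge))
  merged_ids <- vector("list", nrow(hc$merge))
  get_block <- function(k) {
    if (k < 0) list(rows = unname(seqs[-k]), ids = names(seqs)[-k])
    else list(rows = merged_rows[[k]], ids = merged_ids[[k]])
  }
  for (m in seq_len(nrow(hc$merge))) {
    A <- get_block(hc$merge[m, 1])
    B <- get_block(hc$merge[m, 2])
    rows <- align_profiles(A$rows, B$rows)
    merged_rows[[m]] <- rows
    merged_ids[[m]] <- c(A$ids, B$ids)
  }
  rows <- merged_rows[[nrow(hc$merge)]]
  ids <- merged_ids[[nrow(hc$merge)]]
  rows <- rows[match(names(seqs), ids)]
  structure(list(ids = names(seqs),
                 rows = stats::setNames(rows, names(seqs))),
            class = "acs_msa")
}

#' @export
print.acs_msa <- function(x, ...) {
  cat(sprintf("MSA: %d sequences x %d columns\n", length(x$rows),
              nchar(x$rows[1])))
  invisible(x)
}

#' Pairwise distances from a multiple alignment
#'
#' p-distance (mismatches over pairwise-complete columns) or its
#' Poisson correction `d = -ln(1 - p)`, with pairwise deletion of gap
#' columns. A pair with zero comparable columns, or `p = 1` under the
#' Poisson model, is an error naming the pair.
#'
#' @param msa an `acs_msa` (or named equal-length gapped strings).
#' @param model `"poisson"` (default) or `"p"`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
distance_matrix <- function(msa, model = c("poisson", "p")) {
  model <- match.arg(model)
  rows <- if (inherits(msa, "acs_msa")) msa$rows else msa
  if (length(rows) < 2) stop("need >= 2 aligned rows")
  if (length(unique(nchar(rows))) != 1) stop("rows must be equal length")
  ids <- names(rows)
  chs <- do.call(rbind, strsplit(rows, ""))
  n <- length(rows)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- chs[i, ] != "-" & chs[j, ] != "-"
    if (!any(ok))
      stop("no comparable columns for pair ", ids[i], " / ", ids[j])
    p <- mean(chs[i, ok] != chs[j, ok])
    d <- if (model == "p") p else {
      if (p >= 1)
        stop("saturated pair ", ids[i], " / ", ids[j],
             ": Poisson distance infinite")
      -log(1 - p)
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) on a symmetric
#' distance matrix; negative branch-length estimates are clamped to
#' zero, with the originals preserved in
#' `attr(tree, "original_edge_lengths")`.
#'
#' @param D symmetric non-negative distance matrix (>= 3 taxa, zero
#'   diagonal).
#' @return an [ape::phylo] tree (unrooted for >= 4 taxa).
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("need at least 3 taxa")
  if (any(D < 0)) stop("negative distances")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix not symmetric")
  if (any(diag(D) != 0)) stop("nonzero diagonal")
  tree <- ape::nj(D)
  orig <- tree$edge.length
  if (any(orig < 0)) {
    tree$edge.length <- pmax(orig, 0)
    attr(tree, "clamped_edges") <- which(orig < 0)
  }
  attr(tree, "original_edge_lengths") <- orig
  tree
}

# Canonical bipartition signatures of a tree's internal edges.
# Each bipartition is represented by the side NOT containing the
# alphabetically first tip, as a sorted label string.
tree_bipartitions <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  anchor <- sort(labs)[1]
  n <- length(labs)
  sigs <- vapply(pp, function(part) {
    side <- labs[part]
    if (anchor %in% side) side <- setdiff(labs, side)
    paste(sort(side), collapse = "\r")
  }, character(1))
  sizes <- vapply(pp, length, integer(1))
  keep <- sizes >= 2 & sizes <= n - 2
  list(signatures = sigs, informative = keep, labels = labs)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree
#' per replicate, and reports for each internal edge of the full-data
#' tree the percentage of replicates containing the same bipartition.
#' Replicate `r` uses seed `seed + r`, so any replicate is reproducible
#' in isolation.
#'
#' @param msa an `acs_msa`.
#' @param n_replicates bootstrap replicates (default 1000).
#' @param model distance model, see [distance_matrix()].
#' @param seed integer seed.
#' @return the full-data NJ tree with `node.label` set to supports (in
#'   [0, 100]; root/trivial labels empty) and a `support` attribute
#'   (data.frame `signature`, `support`).
#' @export
bootstrap_support <- function(msa, n_replicates = 1000,
                              model = "poisson", seed) {
  if (missing(seed)) stop("seed is required for the bootstrap")
  rows <- msa$rows
  L <- nchar(rows[1])
  if (L < 2) stop("alignment must have >= 2 columns")
  chs <- do.call(rbind, strsplit(rows, ""))
  full <- neighbor_joining(distance_matrix(msa, model = model))
  bp <- tree_bipartitions(full)
  counts <- stats::setNames(numeric(length(bp$signatures)),
                            bp$signatures)
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r)
    cols <- sample.int(L, L, replace = TRUE)
    rrows <- apply(chs[, cols, drop = FALSE], 1, paste, collapse = "")
    names(rrows) <- names(rows)
    rt <- neighbor_joining(distance_matrix(
      structure(list(rows = rrows), class = "acs_msa"), model = model))
    rsig <- tree_bipartitions(rt)$signatures
    hit <- bp$signatures %in% rsig
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / n_replicates
  full$node.label <- ifelse(bp$informative,
                            format(round(support, 1), trim = TRUE), "")
  attr(full, "support") <- data.frame(
    signature = gsub("\r", ",", bp$signatures[bp$informative]),
    support = unname(support[bp$informative]))
  full
}

#' Is a label set monophyletic in an unrooted tree?
#'
#' `TRUE` iff removing some edge bipartitions the leaves into exactly
#' the subset and its complement (singletons, the full set, and
#' complements of singletons are trivially monophyletic).
#'
#' @param tree an [ape::phylo].
#' @param labels character vector of tip labels.
#' @return logical.
#' @export
is_monophyletic <- function(tree, labels) {
  tips <- tree$tip.label
  unknown <- setdiff(labels, tips)
  if (length(unknown))
    stop("unknown labels: ", paste(unknown, collapse = ", "))
  k <- length(unique(labels))
  n <- length(tips)
  if (k %in% c(1L, n - 1L, n)) return(TRUE)
  bp <- tree_bipartitions(tree)
  anchor <- sort(tips)[1]
  side <- unique(labels)
  if (anchor %in% side) side <- setdiff(tips, side)
  sig <- paste(sort(side), collapse = "\r")
  sig %in% bp$signatures[bp$informative]
}

#' Write a tree as Newick text
#'
#' @param tree an [ape::phylo] (node labels carry bootstrap supports).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
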