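# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exact PMF of a quantised PSSM score by enumerating every word of the
# alphabet (feasible for small width x alphabet).
oracle_score_pmf <- function(qmat, bg) {
  w <- nrow(qmat); K <- ncol(qmat)
  words <- as.matrix(expand.grid(rep(list(seq_len(K)), w)))
  scores <- vapply(seq_len(nrow(words)), function(r)
    sum(qmat[cbind(seq_len(w), words[r, ])]), numeric(1))
  probs <- vapply(seq_len(nrow(words)), function(r)
    prod(bg[words[r, ]]), numeric(1))
  tapply(probs, scores, sum)
}

# Upper-tail p-value from the enumeration oracle.
oracle_pvalue <- function(qmat, bg, score) {
  pmf <- oracle_score_pmf(qmat, bg)
  s <- as.numeric(names(pmf))
  sum(pmf[s >= score])
}

# Optimal global affine-gap alignment score by memoised recursion over
# (i, j, state); independent of the package's DP implementation.
# Convention: a gap of length k costs gap_open + k * gap_extend.
oracle_global_score <- function(a, b, subst, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  go <- gap_open + gap_extend; ge <- gap_extend
  memo <- new.env(hash = TRUE)
  # best score of aligning a[1..i] with b[1..j], arriving in `state`
  # (0 = match/mismatch, 1 = gap in b, 2 = gap in a)
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == 0 && j == 0) {
      if (state == 0) 0 else -Inf
    } else if (state == 0) {
      if (i == 0 || j == 0) -Inf
      else subst[av[i], bv[j]] +
        max(rec(i - 1, j - 1, 0), rec(i - 1, j - 1, 1),
            rec(i - 1, j - 1, 2))
    } else if (state == 1) {
      if (i == 0) -Inf
      else max(rec(i - 1, j, 0) - go, rec(i - 1, j, 1) - ge,
               rec(i - 1, j, 2) - go)
    } else {
      if (j == 0) -Inf
      else max(rec(i, j - 1, 0) - go, rec(i, j - 1, 2) - ge,
               rec(i, j - 1, 1) - go)
    }
    memo[[key]] <- val
    val
  }
  max(rec(na, nb, 0), rec(na, nb, 1), rec(na, nb, 2))
}

# Brute-force minimum RMSD over rotations: seeded random unit
# quaternions plus Nelder-Mead refinement in axis-angle coordinates
# around the best candidate. Independent of the SVD route.
oracle_min_rmsd <- function(X, Y, n_quat = 20000, seed = 1) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  rmsd_of_R <- function(R) sqrt(mean(rowSums((Xc - Yc %*% R)^2)))
  quat_to_R <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           nrow = 3, byrow = TRUE)
  }
  set.seed(seed)
  Q <- matrix(rnorm(n_quat * 4), ncol = 4)
  best <- Inf; bestq <- c(1, 0, 0, 0)
  for (r in seq_len(n_quat)) {
    v <- rmsd_of_R(quat_to_R(Q[r, ]))
    if (v < best) { best <- v; bestq <- Q[r, ] }
  }
  f <- function(p) rmsd_of_R(quat_to_R(bestq + p))
  opt <- stats::optim(c(0, 0, 0, 0), f, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  min(best, opt$value)
}

# Random additive distance matrix from a random binary tree topology;
# returns the matrix and the generating ape::phylo.
random_additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(k) runif(k, 0.05, 1))
  tree$tip.label <- sort(tree$tip.label)
  D <- cophenetic(tree)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(D = D, tree = tree)
}
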