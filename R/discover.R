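#' Discover ungapped motifs by ZOOPS expectation-maximisation
#'
#' Greedy sequential motif discovery in the style of MEME: for each
#' candidate width, ZOOPS (zero-or-one occurrence per sequence) EM is run
#' from several seeded starting points; the best motif across widths is
#' kept if it clears the significance floor, its occurrences are
#' probabilistically erased, and the search repeats up to `max_motifs`.
#' Deterministic given `seed`.
#'
#' The significance criterion is the site log-likelihood ratio penalised
#' by the log of the number of possible occurrence configurations (over
#' the sequences carrying a site) and by the expected one-column
#' maximum-likelihood overfit on background per motif column; a motif is
#' kept only when the penalised value is positive and at least two
#' sequences carry a site. Accepted site sets are shift-refined,
#' polished by one EM refit, pruned leave-one-out, and flank-trimmed
#' (see the methods vignette).
#'
#' @param sequences named character vector (or `AAStringSet`) of at least
#'   two protein sequences, each longer than `min_width`.
#' @param widths candidate widths; default a grid spanning
#'   `[min_width, max_width]`: `c(6, 8, 11, 15, 21, 29, 38, 50)`.
#' @param min_width,max_width discovery bounds (defaults 6 and 50).
#' @param max_motifs maximum number of motifs to report (default 25).
#' @param mode occurrence model: `"zoops"` (default) or `"oops"` (one
#'   occurrence per sequence, implemented as ZOOPS with the occurrence
#'   prior pinned at 1).
#' @param n_restarts EM restarts per width (default 20).
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance (defaults 200 and 1e-6).
#' @param pseudocount total pseudocount for the final motif models.
#' @param background optional `acs_background`; default estimated from
#'   `sequences`.
#' @param seed integer seed (required: discovery is stochastic).
#' @return list of `acs_motif` objects in discovery order; each carries
#'   `$sites` (data.frame `sequence_id`, `start`) and `$score_bits` (the
#'   penalised log-likelihood ratio, bits).
#' @export
discover_motifs <- function(sequences, widths = NULL, min_width = 6,
                            max_width = 50, max_motifs = 25,
                            mode = c("zoops", "oops"), n_restarts = 20,
                            max_iter = 200, tol = 1e-6,
                            pseudocount = 0.375, background = NULL,
                            seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is required for motif discovery")
  seqs <- as_seq_vector(sequences)
  if (length(seqs) < 2) stop("need at least 2 sequences")
  if (any(nchar(seqs) <= min_width))
    stop("every sequence must be longer than min_width")
  if (is.null(widths)) {
    widths <- c(6, 8, 11, 15, 21, 29, 38, 50)
    widths <- widths[widths >= min_width & widths <= max_width]
  }
  if (any(widths < min_width | widths > max_width))
    stop("candidate widths must lie in [min_width, max_width]")
  widths <- widths[widths < min(nchar(seqs))]
  if (!length(widths)) stop("no candidate width fits the sequences")
  if (is.null(background)) background <- estimate_background(seqs)
  background <- as_background(background)
  bg <- as.numeric(background)
  enc <- lapply(seqs, encode_seq)
  erase <- lapply(enc, function(e) rep(1, length(e)))
  set.seed(seed)
  motifs <- list()
  for (pass in seq_len(max_motifs)) {
    best <- NULL
    for (w in widths) {
      fit <- em_one_width(enc, seqs, w, bg, erase, mode, n_restarts,
                          max_iter, tol, min_width = min_width)
      if (is.null(fit)) next
      if (is.null(best) || fit$crit_bits > best$crit_bits) best <- fit
    }
    if (is.null(best) || best$crit_bits <= 0 || nrow(best$sites) < 2) break
    inst <- substring(seqs[best$sites$sequence_id], best$sites$start,
                      best$sites$start + best$w - 1L)
    m <- build_motif_model(inst, background, pseudocount = pseudocount,
                           motif_id = sprintf("DM%d", pass),
                           allow_any_width = TRUE)
    m$sites <- best$sites
    m$score_bits <- best$crit_bits
    motifs[[length(motifs) + 1]] <- m
    # probabilistic erasure of the accepted occurrences
    for (k in seq_len(nrow(best$sites))) {
      s <- match(best$sites$sequence_id[k], names(seqs))
      j <- best$sites$start[k]
      z <- best$sites$z[k]
      span <- j:(j + best$w - 1L)
      erase[[s]][span] <- erase[[s]][span] * (1 - z)
    }
  }
  motifs
}
# One discovery pass at a single width: seeded restarts keep the best
# ZOOPS EM fit; the hard site set is then shift-refined (EM can settle
# off by a few columns), polished by one EM refit from the realigned
# model, pruned by a leave-one-out score, and flank-trimmed. The width
# criterion charges each column its expected maximum-likelihood overfit
# on background ((K-1)/2 nats) plus the log number of occurrence
# configurations, so wider candidates do not win by absorbing flanks.
em_one_width <- function(enc, seqs, w, bg, erase, mode, n_restarts,
                         max_iter, tol, min_width = 6L) {
  nseq <- length(enc)
  K <- length(bg)
  m_per_seq <- pmax(lengths(enc) - w + 1L, 0L)
  if (all(m_per_seq < 1L)) return(NULL)
  # cumulative log retention, for window weights at this width
  cum_log_erase <- lapply(erase, function(e)
    c(0, cumsum(pmax(log(pmax(e, 0)), -1e4))))
  log_wt_window <- function(s, j) {
    cl <- cum_log_erase[[s]]
    cl[j + w] - cl[j]
  }
  # seed windows sampled proportionally to their retention weight
  wts <- lapply(seq_len(nseq), function(s) {
    m <- m_per_seq[s]
    if (m < 1) return(numeric(0))
    cl <- cum_log_erase[[s]]
    exp(pmax(cl[(1:m) + w] - cl[1:m], -700))
  })
  flat <- unlist(wts)
  if (sum(flat) <= 0) return(NULL)
  seq_of <- rep(seq_len(nseq), times = vapply(wts, length, integer(1)))
  pos_of <- unlist(lapply(wts, seq_along))
  gamma0 <- if (mode == "oops") 0.999 else 0.5
  theta_from_window <- function(s0, j0) {
    theta0 <- matrix(rep(bg, each = w) * 0.4, nrow = w)
    for (i in seq_len(w)) {
      a <- enc[[s0]][j0 + i - 1L]
      if (a > 0) theta0[i, a] <- theta0[i, a] + 0.6 else
        theta0[i, ] <- bg
    }
    theta0 / rowSums(theta0)
  }
  # seed selection: score a wider pool of candidates by the likelihood
  # after one EM step; run full EM only from the most promising seeds
  n_cand <- min(length(flat), max(30L, 5L * n_restarts))
  cand <- sample.int(length(flat), n_cand, prob = flat,
                     replace = n_cand > sum(flat > 0))
  cand_ll <- vapply(cand, function(pick) {
    cpp_em_zoops(enc, w, theta_from_window(seq_of[pick], pos_of[pick]),
                 bg, gamma0, erase, pseudo = 0.375, maxit = 1,
                 tol = Inf)$loglik
  }, numeric(1))
  top <- cand[order(-cand_ll)][seq_len(min(n_restarts, length(cand)))]
  best <- NULL
  for (pick in top) {
    fit <- cpp_em_zoops(enc, w, theta_from_window(seq_of[pick],
                                                  pos_of[pick]),
                        bg, gamma0, erase,
                        pseudo = 0.375, maxit = max_iter, tol = tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  sites_from_fit <- function(fit) {
    out <- do.call(rbind, lapply(seq_len(nseq), function(s) {
      z <- fit$z[[s]]
      if (!length(z)) return(NULL)
      j <- which.max(z)
      if (z[j] <= 0.5) return(NULL)
      data.frame(sequence_id = names(seqs)[s], start = j, z = z[j])
    }))
    out
  }
  sites <- sites_from_fit(best)
  if (is.null(sites) || nrow(sites) < 2) return(NULL)
  seq_idx <- match(sites$sequence_id, names(seqs))
  # hard-count per-column LLR (nats) of a site set
  col_llrs <- function(starts, idx) {
    vapply(seq_len(w), function(i) {
      a <- vapply(seq_along(starts), function(k)
        enc[[idx[k]]][starts[k] + i - 1L], integer(1))
      a <- a[a > 0]
      if (!length(a)) return(0)
      cnt <- tabulate(a, nbins = K)
      ph <- cnt / length(a)
      nz <- cnt > 0
      sum(cnt[nz] * (log(ph[nz]) - log(bg[nz])))
    }, numeric(1))
  }
  site_llr <- function(starts, idx) {
    sum(col_llrs(starts, idx)) +
      sum(vapply(seq_along(starts), function(k)
        log_wt_window(idx[k], starts[k]), numeric(1)))
  }
  shift_refine <- function(starts, idx) {
    base_llr <- site_llr(starts, idx)
    best_delta <- 0L
    for (delta in setdiff(seq(-(w %/% 2), w %/% 2), 0L)) {
      shifted <- starts + delta
      if (any(shifted < 1L | shifted > m_per_seq[idx])) next
      v <- site_llr(shifted, idx)
      if (v > base_llr + 1e-9) { base_llr <- v; best_delta <- delta }
    }
    starts + best_delta
  }
  sites$start <- shift_refine(sites$start, seq_idx)
  # polish: refit once from the realigned hard-count model, so members
  # a shifted EM optimum left below the posterior cutoff are recovered
  inst <- substring(seqs[sites$sequence_id], sites$start,
                    sites$start + w - 1L)
  cnts <- matrix(0, nrow = w, ncol = K)
  for (k in seq_len(nrow(sites))) {
    a <- enc[[seq_idx[k]]][sites$start[k]:(sites$start[k] + w - 1L)]
    good <- a > 0
    cnts[cbind(which(good), a[good])] <- cnts[cbind(which(good), a[good])] + 1
  }
  theta1 <- (cnts + 0.375 * rep(bg, each = w)) / (nrow(sites) + 0.375)
  theta1 <- theta1 / rowSums(theta1)
  fit2 <- cpp_em_zoops(enc, w, theta1, bg,
                       min(0.999, nrow(sites) / nseq), erase,
                       pseudo = 0.375, maxit = max_iter, tol = tol)
  sites2 <- sites_from_fit(fit2)
  if (!is.null(sites2) && nrow(sites2) >= nrow(sites)) {
    sites <- sites2
    seq_idx <- match(sites$sequence_id, names(seqs))
    sites$start <- shift_refine(sites$start, seq_idx)
  }
  # leave-one-out pruning: each site must beat background against the
  # model built from the remaining sites (guards against the ZOOPS
  # local optimum in which a junk site sustains itself)
  repeat {
    n <- nrow(sites)
    if (n < 3) break
    letmat <- t(vapply(seq_len(n), function(k)
      enc[[seq_idx[k]]][sites$start[k]:(sites$start[k] + w - 1L)],
      integer(w)))
    loo <- vapply(seq_len(n), function(k) {
      sc <- 0
      for (i in seq_len(w)) {
        a <- letmat[k, i]
        if (a == 0L) next
        cnt <- sum(letmat[-k, i] == a)
        ph <- (cnt + 0.375 * bg[a]) / (n - 1 + 0.375)
        sc <- sc + log(ph / bg[a])
      }
      sc
    }, numeric(1))
    drop <- loo < 0
    if (!any(drop) || all(drop)) break
    sites <- sites[!drop, , drop = FALSE]
    seq_idx <- seq_idx[!drop]
  }
  if (nrow(sites) < 2) return(NULL)
  # flank trimming: the selection charge is the expected one-column
  # overfit on background; the trim bar additionally demands ~1.5 nats
  # of evidence per site so weak flanks (and half-absorbed neighbours)
  # are cut before erasure can damage adjacent motifs
  col_llr <- col_llrs(sites$start, seq_idx)
  lambda <- (K - 1) / 2
  trim_bar <- max(lambda, 1.5 * nrow(sites))
  left <- 1L; right <- w
  while (right - left + 1L > min_width && col_llr[left] < trim_bar)
    left <- left + 1L
  while (right - left + 1L > min_width && col_llr[right] < trim_bar)
    right <- right - 1L
  w2 <- right - left + 1L
  sites$start <- sites$start + (left - 1L)
  m2 <- pmax(lengths(enc) - w2 + 1L, 0L)
  log_wt2 <- vapply(seq_len(nrow(sites)), function(k) {
    cl <- cum_log_erase[[seq_idx[k]]]
    cl[sites$start[k] + w2] - cl[sites$start[k]]
  }, numeric(1))
  llr2 <- sum(col_llr[left:right]) + sum(log_wt2)
  crit <- llr2 - sum(log(m2[seq_idx] + 1)) - lambda * w2
  rownames(sites) <- NULL
  list(w = w2, sites = sites, llr_nats = llr2,
       crit_bits = crit / log(2), loglik = best$loglik)
}
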