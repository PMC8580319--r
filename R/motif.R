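#' Build an ungapped probabilistic motif from aligned instances
#'
#' Constructs a position probability matrix from equal-length ungapped
#' instance strings, with a background-weighted pseudocount, and derives
#' the log-odds (bits) scoring matrix relative to the background:
#' `log_odds[i, a] = log2(prob[i, a] / background[a])`.
#'
#' @param instances character vector of equal-length instance strings.
#' @param background an `acs_background` (see [estimate_background()]).
#' @param pseudocount non-negative total pseudocount, distributed across
#'   letters proportionally to the background (MEME-style). Default
#'   `0.375`.
#' @param motif_id label for the motif (e.g. `"ACS1"`).
#' @param allow_any_width if `TRUE`, widths outside the discovery bound
#'   `[6, 50]` are allowed (for toy models and tests).
#' @return an object of class `acs_motif` with elements `motif_id`,
#'   `width`, `nsites`, `counts`, `prob`, `log_odds`, `background`,
#'   `consensus`.
#' @examples
#' bg <- uniform_background()
#' m <- build_motif_model(c("ACDEFG", "ACDEFG"), bg, pseudocount = 0)
#' m$consensus
#' @export
build_motif_model <- function(instances, background, pseudocount = 0.375,
                              motif_id = "motif", allow_any_width = FALSE) {
  background <- as_background(background)
  instances <- as_seq_vector(instances)
  if (length(instances) == 0L) stop("zero motif instances")
  w <- unique(nchar(instances))
  if (length(w) != 1L)
    stop("ragged instance lengths: ", paste(sort(w), collapse = ", "))
  if (!allow_any_width && (w < 6 || w > 50))
    stop("motif width ", w, " outside the discovery bound [6, 50]; ",
         "use allow_any_width = TRUE to override")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  counts <- matrix(0, nrow = w, ncol = 20, dimnames = list(NULL, AA_LETTERS))
  n_eff <- numeric(w)
  for (s in instances) {
    idx <- encode_seq(s)
    keep <- idx > 0L
    pos <- which(keep)
    counts[cbind(pos, idx[keep])] <- counts[cbind(pos, idx[keep])] + 1
    n_eff[keep] <- n_eff[keep] + 1
  }
  prob <- (counts + pseudocount * rep(background, each = w)) /
    (n_eff + pseudocount)
  prob[!is.finite(prob)] <- rep(background, each = w)[!is.finite(prob)]
  prob <- prob / rowSums(prob)
  new_motif(motif_id, counts, prob, background, nsites = length(instances))
}

new_motif <- function(motif_id, counts, prob, background, nsites) {
  w <- nrow(prob)
  lo <- log2(sweep(prob, 2, unclass(background), "/"))
  consensus <- paste(AA_LETTERS[max.col(prob, ties.method = "first")],
                     collapse = "")
  structure(list(motif_id = motif_id, width = w, nsites = nsites,
                 counts = counts, prob = prob, log_odds = lo,
                 background = background, consensus = consensus),
            class = "acs_motif")
}

#' @export
print.acs_motif <- function(x, ...) {
  cat(sprintf("Motif %s: width %d, nsites %s, consensus %s\n",
              x$motif_id, x$width, format(x$nsites), x$consensus))
  invisible(x)
}

# Quantised integer log-odds for exact p-values. Scores are rounded DOWN
# (floor) so tail p-values are conservative.
quantise_motif <- function(motif, scale = 1000L) {
  v <- floor(motif$log_odds * scale)
  # clamp -Inf (prob 0 with zero pseudocount) to a deep but finite score
  v[!is.finite(v) | v < -100 * scale] <- -100 * scale
  matrix(as.integer(v), nrow = motif$width)
}

#' Write motifs in MEME minimal text format
#'
#' Serialises a list of motifs as MEME minimal motif format (version 4):
#' an `ALPHABET` line, `Background letter frequencies`, and one
#' `letter-probability matrix` block per motif.
#'
#' @param motifs a single `acs_motif` or a list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path) {
  if (inherits(motifs, "acs_motif")) motifs <- list(motifs)
  bg <- motifs[[1]]$background
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               paste0("ALPHABET= ", paste(AA_LETTERS, collapse = "")), "",
               "Background letter frequencies"), con)
  writeLines(paste(sprintf("%s %.6f", AA_LETTERS, bg), collapse = " "), con)
  for (m in motifs) {
    writeLines(c("", paste0("MOTIF ", m$motif_id),
                 sprintf(
                   "letter-probability matrix: alength= 20 w= %d nsites= %d E= 0",
                   m$width, round(m$nsites))), con)
    for (i in seq_len(m$width))
      writeLines(paste(sprintf("%.6f", m$prob[i, ]), collapse = " "), con)
  }
  invisible(path)
}

#' Read motifs from MEME minimal text format
#'
#' Parses the MEME minimal motif format (as produced by the MEME suite or
#' [write_meme()]): background frequencies plus one letter-probability
#' matrix per motif. Probabilities are renormalised row-wise and counts
#' reconstructed as `prob * nsites`.
#'
#' @param path path to a MEME minimal format file.
#' @param background optional `acs_background` overriding the file's
#'   background for log-odds.
#' @return a named list of `acs_motif` objects, in file order.
#' @export
read_meme <- function(path, background = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  alpha_i <- grep("^ALPHABET", lines)
  alphabet <- AA_LETTERS
  if (length(alpha_i)) {
    a <- sub("^ALPHABET=\\s*", "", lines[alpha_i[1]])
    alphabet <- strsplit(a, "")[[1]]
    if (!identical(sort(alphabet), sort(AA_LETTERS)))
      stop("only the 20-letter protein alphabet is supported")
  }
  bg <- uniform_background()
  bi <- grep("^Background letter frequencies", lines)
  if (length(bi)) {
    toks <- character(0)
    j <- bi[1] + 1
    while (j <= length(lines) && !grepl("^MOTIF", lines[j]) &&
           nzchar(lines[j])) {
      toks <- c(toks, strsplit(lines[j], "\\s+")[[1]])
      j <- j + 1
    }
    lets <- toks[seq(1, length(toks), by = 2)]
    vals <- as.numeric(toks[seq(2, length(toks), by = 2)])
    v <- vals[match(AA_LETTERS, lets)]
    if (!anyNA(v)) bg <- as_background(v / sum(v))
  }
  if (!is.null(background)) bg <- as_background(background)
  out <- list()
  mi <- grep("^MOTIF", lines)
  for (k in seq_along(mi)) {
    id <- strsplit(lines[mi[k]], "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix", lines)
    hdr <- hdr[hdr > mi[k]][1]
    if (is.na(hdr)) stop("MOTIF ", id, " has no letter-probability matrix")
    get_num <- function(key, default) {
      m <- regmatches(lines[hdr],
                      regexpr(paste0(key, "=\\s*[0-9.eE+-]+"), lines[hdr]))
      if (!length(m)) return(default)
      as.numeric(sub(paste0(key, "=\\s*"), "", m))
    }
    w <- get_num("w", NA)
    nsites <- get_num("nsites", 20)
    if (is.na(w)) stop("MOTIF ", id, ": width missing")
    rows <- lines[(hdr + 1):(hdr + w)]
    prob <- do.call(rbind, lapply(strsplit(rows, "\\s+"), as.numeric))
    if (ncol(prob) != 20) stop("MOTIF ", id, ": expected 20 columns")
    colnames(prob) <- alphabet
    prob <- prob[, AA_LETTERS, drop = FALSE]
    prob <- prob / rowSums(prob)
    counts <- prob * nsites
    out[[id]] <- new_motif(id, counts, prob, bg, nsites = nsites)
  }
  out
}
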