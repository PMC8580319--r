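#' Read a crystal structure from a PDB file
#'
#' Parses a PDB file via [bio3d::read.pdb()] into a flat atom table.
#' Alternate locations are resolved by keeping the highest-occupancy
#' conformer (ties broken by alphabetical altloc); heteroatoms (ligands
#' such as the PLP-aminoethoxyvinylglycine adduct PPG) are retained and
#' flagged. Only PDB text is supported; mmCIF input is rejected with a
#' clear error.
#'
#' @param path path to a PDB file.
#' @param id structure identifier (default: file base name).
#' @return an object of class `acs_structure`: list with `id` and
#'   `atoms`, a data.frame with columns `type`, `eleno`, `elety`,
#'   `element`, `resid`, `chain`, `resno`, `insert`, `x`, `y`, `z`,
#'   `occ`, `het`.
#' @export
read_structure <- function(path, id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
    stop("mmCIF input is not supported; provide PDB text")
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  a <- pdb$atom
  insert <- a$insert
  insert[is.na(insert)] <- ""
  alt <- a$alt
  alt[is.na(alt)] <- ""
  atoms <- data.frame(type = a$type, eleno = a$eleno, elety = a$elety,
                      element = if (!is.null(a$elesy)) a$elesy else
                        sub("^[0-9]*", "", substr(a$elety, 1, 1)),
                      resid = a$resid, chain = a$chain, resno = a$resno,
                      insert = insert, x = a$x, y = a$y, z = a$z,
                      occ = ifelse(is.na(a$o), 1, a$o), alt = alt,
                      het = a$type == "HETATM",
                      stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x + atoms$y + atoms$z)))
    stop("non-finite coordinates in ", path)
  # altloc resolution: highest occupancy, ties to the alphabetically
  # first conformer
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety,
               sep = "|")
  ord <- order(key, -atoms$occ, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$insert,
                       atoms$eleno), , drop = FALSE]
  rownames(atoms) <- NULL
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  structure(list(id = id, atoms = atoms), class = "acs_structure")
}

#' Write an `acs_structure` as minimal PDB text
#'
#' @param struct an `acs_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(struct, path) {
  a <- struct$atoms
  bio3d::write.pdb(file = path,
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, eleno = a$eleno,
                   elety = a$elety, chain = a$chain,
                   insert = ifelse(a$insert == "", NA, a$insert),
                   o = a$occ)
  invisible(path)
}

#' Build an `acs_structure` from coordinates
#'
#' Convenience constructor used by the synthetic fixture generator: one
#' pseudo-chain of alanine residues with one CA atom per point.
#'
#' @param xyz n x 3 numeric matrix (Angstrom).
#' @param chain chain identifier (default "A").
#' @param id structure id.
#' @return an `acs_structure`.
#' @export
structure_from_xyz <- function(xyz, chain = "A", id = "synthetic") {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3)
  n <- nrow(xyz)
  atoms <- data.frame(type = "ATOM", eleno = seq_len(n), elety = "CA",
                      element = "C", resid = "ALA", chain = chain,
                      resno = seq_len(n), insert = "", x = xyz[, 1],
                      y = xyz[, 2], z = xyz[, 3], occ = 1, alt = "",
                      het = FALSE, stringsAsFactors = FALSE)
  structure(list(id = id, atoms = atoms), class = "acs_structure")
}

#' @export
print.acs_structure <- function(x, ...) {
  ch <- chains(x)
  cat(sprintf("Structure %s: %d atoms, %d protein chain(s) [%s], %d het atoms\n",
              x$id, nrow(x$atoms), length(ch), paste(ch, collapse = ","),
              sum(x$atoms$het)))
  invisible(x)
}

#' Protein chain identifiers of a structure
#'
#' @param struct an `acs_structure`.
#' @return character vector of chain ids containing protein atoms.
#' @export
chains <- function(struct) {
  sort(unique(struct$atoms$chain[!struct$atoms$het]))
}

#' One-letter sequence of a protein chain
#'
#' @param struct an `acs_structure`.
#' @param chain chain identifier.
#' @return list with `sequence` (string) and `resno` (per-residue
#'   numbers, ordered as in the sequence).
#' @export
chain_sequence <- function(struct, chain) {
  a <- struct$atoms
  a <- a[!a$het & a$chain == chain & a$elety == "CA", , drop = FALSE]
  a <- a[order(a$resno, a$insert), , drop = FALSE]
  list(sequence = paste(bio3d::aa321(a$resid), collapse = ""),
       resno = a$resno, insert = a$insert)
}

ca_table <- function(struct, chain) {
  a <- struct$atoms
  a <- a[!a$het & a$chain == chain & a$elety == "CA", , drop = FALSE]
  a[order(a$resno, a$insert), , drop = FALSE]
}

#' Pair equivalent atoms of two structures
#'
#' Pairs selected atoms (default CA) of one or more chain pairs, either
#' by identical residue number + insertion code (within the same entry)
#' or via global sequence alignment of the chain sequences (across
#' different proteins). Residues missing the selected atom on either
#' side are dropped and counted.
#'
#' @param structA,structB `acs_structure` objects.
#' @param chainsA,chainsB equal-length chain id vectors; chain slot `k`
#'   of A is paired with slot `k` of B. Defaults: all protein chains.
#' @param mode `"resno"` or `"alignment"`.
#' @param ... alignment parameters passed to [global_align()].
#' @return an object of class `acs_pairing`: list with `X`, `Y` (n x 3
#'   coordinate matrices), `pairs` (data.frame of chain/resno on both
#'   sides), `n_unpaired_A`, `n_unpaired_B`.
#' @export
pair_atoms <- function(structA, structB, chainsA = NULL, chainsB = NULL,
                       mode = c("resno", "alignment"), ...) {
  mode <- match.arg(mode)
  if (is.null(chainsA)) chainsA <- chains(structA)
  if (is.null(chainsB)) chainsB <- chains(structB)
  if (length(chainsA) != length(chainsB))
    stop("chainsA and chainsB must pair one-to-one")
  rows <- list()
  unpA <- 0L; unpB <- 0L
  for (k in seq_along(chainsA)) {
    ta <- ca_table(structA, chainsA[k])
    tb <- ca_table(structB, chainsB[k])
    if (mode == "resno") {
      ka <- paste(ta$resno, ta$insert)
      kb <- paste(tb$resno, tb$insert)
      common <- intersect(ka, kb)
      ia <- match(common, ka); ib <- match(common, kb)
    } else {
      sa <- paste(bio3d::aa321(ta$resid), collapse = "")
      sb <- paste(bio3d::aa321(tb$resid), collapse = "")
      aln <- global_align(sa, sb, ...)
      keep <- aln$query_index > 0 & aln$reference_index > 0
      ia <- aln$query_index[keep]; ib <- aln$reference_index[keep]
    }
    unpA <- unpA + nrow(ta) - length(ia)
    unpB <- unpB + nrow(tb) - length(ib)
    if (length(ia))
      rows[[k]] <- data.frame(chainA = chainsA[k], resnoA = ta$resno[ia],
                              chainB = chainsB[k], resnoB = tb$resno[ib],
                              xA = ta$x[ia], yA = ta$y[ia], zA = ta$z[ia],
                              xB = tb$x[ib], yB = tb$y[ib], zB = tb$z[ib])
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || nrow(pairs) == 0) stop("zero atom pairs")
  structure(list(X = as.matrix(pairs[, c("xA", "yA", "zA")]),
                 Y = as.matrix(pairs[, c("xB", "yB", "zB")]),
                 pairs = pairs[, 1:4],
                 n_unpaired_A = unpA, n_unpaired_B = unpB),
            class = "acs_pairing")
}

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimising the
#' root-mean-square deviation between `X` and `Y %*% R + t` (reflections
#' excluded), via singular value decomposition of the cross-covariance
#' matrix.
#'
#' @param X,Y n x 3 coordinate matrices of paired atoms (n >= 3,
#'   non-collinear), or an `acs_pairing`.
#' @return an object of class `acs_superposition`: list with `rotation`
#'   (3 x 3, det +1), `translation` (length 3), `rmsd` (Angstrom),
#'   `n_atoms`, and `Yfit` (the transformed `Y`).
#' @export
kabsch_superpose <- function(X, Y = NULL) {
  if (inherits(X, "acs_pairing")) { Y <- X$Y; X <- X$X }
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(ncol(X) == 3, ncol(Y) == 3, nrow(X) == nrow(Y))
  n <- nrow(X)
  if (n < 3) stop("need at least 3 atom pairs")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sx <- svd(Xc)$d; sy <- svd(Yc)$d
  if (sx[2] < 1e-8 * max(sx[1], 1) || sy[2] < 1e-8 * max(sy[1], 1))
    stop("degenerate (collinear) configuration")
  H <- crossprod(Yc, Xc)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  Yrot <- Yc %*% R
  rmsd <- sqrt(mean(rowSums((Xc - Yrot)^2)))
  structure(list(rotation = R, translation = as.numeric(cx - cy %*% R),
                 rmsd = rmsd, n_atoms = n,
                 Yfit = sweep(Yrot, 2, cx, "+")),
            class = "acs_superposition")
}

#' @export
print.acs_superposition <- function(x, ...) {
  cat(sprintf("Superposition over %d atoms: rmsd %.3f A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

#' Residues contacting a bound ligand
#'
#' Lists every protein residue with at least one non-hydrogen atom
#' within `radius` of any atom of the named het group. Residues from a
#' different chain than the ligand copy are flagged cross-subunit (the
#' hallmark of the glutamine reaching into the partner subunit's active
#' site).
#'
#' @param struct an `acs_structure`.
#' @param ligand het residue name (default `"PPG"`).
#' @param radius contact radius in Angstrom (default 4.0).
#' @return data.frame: `ligand_chain`, `ligand_resno`, `chain`, `resno`,
#'   `resid`, `min_dist`, `cross_subunit`, sorted by ligand copy then
#'   distance.
#' @export
active_site <- function(struct, ligand = "PPG", radius = 4.0) {
  a <- struct$atoms
  lig <- a[a$het & a$resid == ligand, , drop = FALSE]
  if (nrow(lig) == 0) {
    avail <- sort(unique(a$resid[a$het]))
    stop("ligand ", ligand, " not found; het groups present: ",
         if (length(avail)) paste(avail, collapse = ", ") else "none")
  }
  prot <- a[!a$het & !grepl("^[0-9]*H", a$elety), , drop = FALSE]
  if (radius <= 0 || nrow(prot) == 0)
    return(data.frame(ligand_chain = character(0),
                      ligand_resno = integer(0), chain = character(0),
                      resno = integer(0), resid = character(0),
                      min_dist = numeric(0), cross_subunit = logical(0)))
  P <- as.matrix(prot[, c("x", "y", "z")])
  out <- list()
  for (lk in unique(paste(lig$chain, lig$resno))) {
    lsub <- lig[paste(lig$chain, lig$resno) == lk, , drop = FALSE]
    lsub <- lsub[!grepl("^[0-9]*H", lsub$elety), , drop = FALSE]
    L <- as.matrix(lsub[, c("x", "y", "z")])
    # min distance from each protein atom to any ligand atom
    d2 <- apply(L, 1, function(p)
      (P[, 1] - p[1])^2 + (P[, 2] - p[2])^2 + (P[, 3] - p[3])^2)
    mind <- sqrt(if (is.matrix(d2)) apply(d2, 1, min) else min(d2))
    hit <- mind <= radius
    if (!any(hit)) next
    h <- prot[hit, , drop = FALSE]
    h$min_dist <- mind[hit]
    agg <- stats::aggregate(min_dist ~ chain + resno + resid, data = h,
                            FUN = min)
    agg$ligand_chain <- lsub$chain[1]
    agg$ligand_resno <- lsub$resno[1]
    agg$cross_subunit <- agg$chain != lsub$chain[1]
    out[[lk]] <- agg[order(agg$min_dist),
                     c("ligand_chain", "ligand_resno", "chain", "resno",
                       "resid", "min_dist", "cross_subunit")]
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(ligand_chain = character(0),
                      ligand_resno = integer(0), chain = character(0),
                      resno = integer(0), resid = character(0),
                      min_dist = numeric(0), cross_subunit = logical(0))
  rownames(res) <- NULL
  res
}

#' Superpose a restricted residue region of two structures
#'
#' Restricts the atom pairing to a list of residues and either
#' superposes that region by least squares, or (with
#' `frozen_frame = TRUE`) measures the raw RMSD in the current global
#' frame, e.g. after a whole-chain superposition.
#'
#' @param structA,structB `acs_structure` objects.
#' @param residues integer vector of residue numbers (on structure A's
#'   numbering for `"resno"` mode; positions in chain A's sequence for
#'   `"alignment"` mode they are mapped through the alignment).
#' @param chainsA,chainsB chain pairing as in [pair_atoms()].
#' @param mode pairing mode, see [pair_atoms()].
#' @param frozen_frame if `TRUE`, no new superposition is performed.
#' @param ... alignment parameters.
#' @return an `acs_superposition` (for `frozen_frame = TRUE` the
#'   rotation is identity and `rmsd` is the frame RMSD).
#' @export
compare_regions <- function(structA, structB, residues = NULL,
                            chainsA = NULL, chainsB = NULL,
                            mode = c("resno", "alignment"),
                            frozen_frame = FALSE, ...) {
  mode <- match.arg(mode)
  pr <- pair_atoms(structA, structB, chainsA, chainsB, mode = mode, ...)
  if (!is.null(residues)) {
    keep <- pr$pairs$resnoA %in% residues
    miss <- setdiff(residues, pr$pairs$resnoA)
    if (length(miss))
      stop("residues not resolvable in both structures: ",
           paste(miss, collapse = ", "))
    pr$X <- pr$X[keep, , drop = FALSE]
    pr$Y <- pr$Y[keep, , drop = FALSE]
    pr$pairs <- pr$pairs[keep, , drop = FALSE]
  }
  if (frozen_frame) {
    rmsd <- sqrt(mean(rowSums((pr$X - pr$Y)^2)))
    return(structure(list(rotation = diag(3), translation = c(0, 0, 0),
                          rmsd = rmsd, n_atoms = nrow(pr$X),
                          Yfit = pr$Y),
                     class = "acs_superposition"))
  }
  kabsch_superpose(pr)
}
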