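#' Recompute the printed structural comparison RMSDs
#'
#' Given a directory containing the deposited coordinate files
#' `7DLW.pdb` (wild-type AtACS7-PPG, two dimers per asymmetric unit),
#' `7DLY.pdb` (the AtACS7-R6 box-swap mutant dimer) and `1M7Y.pdb`
#' (MdACS1-PPG), recomputes the six published comparison RMSDs:
#' the 7DLW A/B vs C/D dimer fit (0.76 A), the C vs D subunit fit
#' (0.44 A), the AtACS7 vs MdACS1 overall C-alpha fit (0.83 A) and
#' active-site-residue fit (0.176 A), the wild-type vs R6 dimer fit
#' (0.59 A), and the R6 subunit fit (0.12 A). All fits are
#' single-pass C-alpha least squares; cross-protein pairings use global
#' sequence alignment, within-entry pairings use residue numbers.
#'
#' @param dir directory holding the three PDB files.
#' @param active_site_radius contact radius (Angstrom) used to define
#'   the active-site residue set on 7DLW chain C/D (default 4.0).
#' @return data.frame with columns `comparison`, `printed_rmsd`,
#'   `computed_rmsd`, `n_atoms`.
#' @export
reproduce_printed_rmsds <- function(dir, active_site_radius = 4.0) {
  find_pdb <- function(code) {
    hits <- list.files(dir, pattern = paste0("(?i)^", code, "\\.(pdb|ent)$"),
                       full.names = TRUE)
    if (!length(hits))
      stop("coordinate file for ", code, " not found in ", dir)
    hits[1]
  }
  wt <- read_structure(find_pdb("7dlw"), id = "7DLW")
  r6 <- read_structure(find_pdb("7dly"), id = "7DLY")
  md <- read_structure(find_pdb("1m7y"), id = "1M7Y")
  res <- list()
  add <- function(name, printed, sp)
    res[[length(res) + 1]] <<- data.frame(
      comparison = name, printed_rmsd = printed,
      computed_rmsd = sp$rmsd, n_atoms = sp$n_atoms)
  add("7DLW dimer A/B vs C/D", 0.76,
      kabsch_superpose(pair_atoms(wt, wt, c("A", "B"), c("C", "D"),
                                  mode = "resno")))
  add("7DLW subunit C vs D", 0.44,
      kabsch_superpose(pair_atoms(wt, wt, "C", "D", mode = "resno")))
  mdch <- chains(md)[1]
  add("AtACS7 vs MdACS1 overall (CA)", 0.83,
      kabsch_superpose(pair_atoms(wt, md, "C", mdch,
                                  mode = "alignment")))
  site <- active_site(wt, "PPG", radius = active_site_radius)
  site <- site[site$ligand_chain %in% c("C", "D") & site$chain == "C", ]
  add("AtACS7 vs MdACS1 active site (CA)", 0.176,
      compare_regions(wt, md, residues = unique(site$resno),
                      chainsA = "C", chainsB = mdch,
                      mode = "alignment"))
  r6ch <- chains(r6)
  add("7DLW C/D vs 7DLY dimer", 0.59,
      kabsch_superpose(pair_atoms(wt, r6, c("C", "D"), r6ch[1:2],
                                  mode = "resno")))
  add("7DLY subunit 1 vs 2", 0.12,
      kabsch_superpose(pair_atoms(r6, r6, r6ch[1], r6ch[2],
                                  mode = "resno")))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
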