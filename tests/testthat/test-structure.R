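test_that("PDB fixtures round-trip through write and read", {
  xyz <- synthetic_ca_trace(20, seed = 2)
  st <- structure_from_xyz(xyz, chain = "A", id = "fix")
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(st, path)
  back <- read_structure(path)
  expect_equal(chains(back), "A")
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               round(xyz, 3), ignore_attr = TRUE)
  expect_error(read_structure("nope.cif"), "no such file")
  cif <- withr::local_tempfile(fileext = ".cif")
  writeLines("data_x", cif)
  expect_error(read_structure(cif), "mmCIF")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
            "ATOM", 1, " CA ", "A", "ALA", "A", 1, " ", 1, 0, 0, 0.4, 10),
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
            "ATOM", 2, " CA ", "B", "ALA", "A", 1, " ", 2, 0, 0, 0.6, 10),
    "END"), path)
  st <- read_structure(path)
  expect_equal(nrow(st$atoms), 1L)
  expect_equal(st$atoms$x, 2)
})

test_that("Kabsch superposition is exact on rigid copies", {
  X <- synthetic_ca_trace(30, seed = 5)
  expect_equal(kabsch_superpose(X, X)$rmsd, 0)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Y <- X %*% R + matrix(rep(c(5, -3, 11), each = 30), ncol = 3)
  sp <- kabsch_superpose(X, Y)
  expect_lt(sp$rmsd, 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  expect_equal(crossprod(sp$rotation), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(kabsch_superpose(X[1:2, ], Y[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 0.1), "collinear")
})

test_that("rmsd is symmetric and invariant to rigid pre-transformations", {
  set.seed(6)
  X <- matrix(rnorm(8 * 3, sd = 4), ncol = 3)
  Y <- X + matrix(rnorm(8 * 3, sd = 0.7), ncol = 3)
  r1 <- kabsch_superpose(X, Y)$rmsd
  r2 <- kabsch_superpose(Y, X)$rmsd
  expect_equal(r1, r2, tolerance = 1e-12)
  th <- -1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  expect_equal(kabsch_superpose(X, Y %*% R + 3)$rmsd, r1,
               tolerance = 1e-9)
})

test_that("Kabsch equals the quaternion-grid brute force", {
  set.seed(8)
  for (k in 1:6) {
    n <- sample(4:10, 1)
    X <- matrix(rnorm(n * 3, sd = 3), ncol = 3)
    Y <- X + matrix(rnorm(n * 3, sd = 0.5), ncol = 3)
    expect_equal(kabsch_superpose(X, Y)$rmsd,
                 oracle_min_rmsd(X, Y, n_quat = 8000, seed = k),
                 tolerance = 1e-4)
  }
})

test_that("atom pairing drops unmatched residues and counts them", {
  xyz <- synthetic_ca_trace(40, seed = 9)
  a <- structure_from_xyz(xyz, chain = "A", id = "full")
  b <- structure_from_xyz(xyz[6:40, ], chain = "A", id = "trunc")
  b$atoms$resno <- 6:40
  pr <- pair_atoms(a, b, "A", "A", mode = "resno")
  expect_equal(nrow(pr$X), 35)
  expect_equal(pr$n_unpaired_A, 5)
  self <- pair_atoms(a, a, "A", "A", mode = "resno")
  expect_equal(nrow(self$X), 40)
  expect_lt(kabsch_superpose(pr)$rmsd, 1e-12)
})

test_that("sequence-alignment pairing is bounded by the shorter chain", {
  xyz <- synthetic_ca_trace(30, seed = 10)
  a <- structure_from_xyz(xyz, chain = "A")
  b <- structure_from_xyz(xyz[1:18, ], chain = "B")
  pr <- pair_atoms(a, b, "A", "B", mode = "alignment")
  expect_lte(nrow(pr$X), 18)
})

test_that("region comparison reduces to whole-chain Kabsch and honours a frozen frame", {
  xyz <- synthetic_ca_trace(50, seed = 11)
  a <- structure_from_xyz(xyz, chain = "A")
  pert <- perturb_coordinates(xyz, 0.5, seed = 12)
  b <- structure_from_xyz(pert, chain = "A")
  whole <- compare_regions(a, b, residues = 1:50, mode = "resno")
  direct <- kabsch_superpose(pair_atoms(a, b, mode = "resno"))
  expect_equal(whole$rmsd, direct$rmsd, tolerance = 1e-12)
  expect_error(compare_regions(a, b, residues = c(2, 99), mode = "resno"),
               "not resolvable")
  # displace a region rigidly by exactly 1 A; in the frozen global frame
  # its rmsd is exactly 1
  shifted <- xyz
  shifted[10:20, 1] <- shifted[10:20, 1] + 1
  cshift <- structure_from_xyz(shifted, chain = "A")
  frozen <- compare_regions(a, cshift, residues = 10:20, mode = "resno",
                            frozen_frame = TRUE)
  expect_equal(frozen$rmsd, 1, tolerance = 1e-12)
})

test_that("active-site detection respects the contact radius exactly", {
  # one ligand atom at the origin; residues at controlled distances
  atoms <- data.frame(
    type = c("ATOM", "ATOM", "ATOM", "HETATM"),
    eleno = 1:4, elety = c("CA", "CA", "CA", "C1"),
    element = c("C", "C", "C", "C"),
    resid = c("ALA", "GLY", "TRP", "PPG"),
    chain = c("A", "A", "B", "A"),
    resno = c(1, 2, 3, 900), insert = "",
    x = c(4.01, 3.99, 1.0, 0), y = 0, z = 0,
    occ = 1, alt = "", het = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  st <- structure(list(id = "toy", atoms = atoms),
                  class = "acs_structure")
  rep4 <- active_site(st, "PPG", radius = 4.0)
  expect_setequal(rep4$resno, c(2, 3))
  expect_true(rep4$cross_subunit[rep4$resno == 3])
  expect_false(rep4$cross_subunit[rep4$resno == 2])
  rep_wide <- active_site(st, "PPG", radius = 4.02)
  expect_setequal(rep_wide$resno, c(1, 2, 3))
  expect_equal(nrow(active_site(st, "PPG", radius = 0)), 0)
  expect_error(active_site(st, "PLP"), "PPG")
})

test_that("known-rmsd perturbations are recovered to machine precision", {
  xyz <- synthetic_ca_trace(400, seed = 13)
  expect_identical(perturb_coordinates(xyz, 0, seed = 1), xyz)
  for (target in c(0.12, 0.44, 0.76)) {
    pert <- perturb_coordinates(xyz, target, seed = 14)
    expect_equal(kabsch_superpose(xyz, pert)$rmsd, target,
                 tolerance = 1e-9)
    # extra rigid motion leaves the measured rmsd unchanged
    th <- 0.4
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3)
    expect_equal(kabsch_superpose(xyz, pert %*% R + 7)$rmsd, target,
                 tolerance = 1e-9)
  }
})
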