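test_that("PDB reading echoes printed fields and round-trips at format precision", {
  p <- write_tiny_pdb(withr::local_tempfile(fileext = ".pdb"))
  s <- read_structure(p)
  expect_equal(nrow(s$atoms), 3)
  expect_equal(s$atoms$x, c(11.104, 11.639, 10.729))
  expect_equal(s$atoms$name, c("N", "CA", "C"))
  expect_equal(s$atoms$resno, rep(1L, 3))
  expect_false(any(s$atoms$het))

  out <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, out)
  s2 <- read_structure(out)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(coords(s2), coords(s), tolerance = 1e-3)
})

test_that("degenerate and malformed PDB inputs are rejected with context", {
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), empty)
  expect_error(read_structure(empty), "no ATOM")

  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504",
    "ATOM      2  CA  ALA A   1      11.6xx   6.071  -5.147"), bad)
  expect_error(read_structure(bad), "line 2")
})

test_that("dummy particles are written as HETATM with the reserved residue name", {
  p <- write_tiny_pdb(withr::local_tempfile(fileext = ".pdb"))
  s <- add_dummy_atoms(read_structure(p), list(N1 = c(0, 0, 5)))
  out <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, out)
  lines <- readLines(out)
  expect_length(grep("^HETATM.*DUM", lines), 1)

  s$atoms$chain <- "AB"
  expect_error(write_structure(s, out), "single character")
})

test_that("V2000 molecular graphs are parsed and validated", {
  e <- read_molecule_graph(write_ethane_mol(withr::local_tempfile(fileext = ".mol")))
  expect_equal(sum(e$elements == "C"), 2)
  expect_equal(sum(e$elements == "H"), 6)
  expect_equal(nrow(e$bonds), 7)

  b <- read_molecule_graph(write_benzene_mol(withr::local_tempfile(fileext = ".mol")))
  expect_equal(b$elements, rep("C", 6))
  # 6-cycle: every atom has exactly two neighbours
  deg <- tabulate(c(b$bonds), 6)
  expect_equal(deg, rep(2L, 6))

  badpath <- withr::local_tempfile(fileext = ".mol")
  atoms <- c(mol_atom_line(0, 0, 0, "C"), mol_atom_line(1.5, 0, 0, "C"))
  writeLines(mol_block(2, 1, atoms, mol_bond_line(1, 7)), badpath)
  expect_error(read_molecule_graph(badpath), "nonexistent atom")

  mismatch <- withr::local_tempfile(fileext = ".mol")
  writeLines(mol_block(3, 1, atoms, mol_bond_line(1, 2)), mismatch)
  expect_error(read_molecule_graph(mismatch), "inconsistent")
})

test_that("prmtop dihedral entries decode by |entry|/3 + 1 with impropers excluded", {
  expect_equal(decode_prmtop_dihedrals(matrix(c(0, 3, 6, 9, 5), 1)),
               matrix(1:4, 1))
  # negative fourth index marks an improper: excluded
  out <- decode_prmtop_dihedrals(rbind(c(0, 3, 6, 9, 5),
                                       c(3, 6, 9, -9, 2)))
  expect_equal(nrow(out), 1)
  # negative third index is only the 1-4 exclusion marker: retained
  out2 <- decode_prmtop_dihedrals(matrix(c(0, 3, -6, 9, 5), 1))
  expect_equal(out2, matrix(1:4, 1))
  expect_error(decode_prmtop_dihedrals(matrix(c(0, 4, 6, 9, 5), 1)),
               "divisible by 3")
})

test_that("prmtop dihedral section text is parsed from a hand-built topology", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("%FLAG DIHEDRALS_WITHOUT_HYDROGEN",
               "%FORMAT(10I8)",
               "       0       3       6       9       1       3       6       9     -12       2",
               "       0       3      -6       9       1"), p)
  out <- read_prmtop_dihedrals(p)
  # improper (negative 4th) dropped, 1-4 marker (negative 3rd) kept
  expect_equal(out, rbind(c(1L, 2L, 3L, 4L), c(1L, 2L, 3L, 4L)))
})

test_that("global alignment pairs match exhaustive expectations and an independent oracle", {
  ident <- global_sequence_align("ACDEF", "ACDEF")
  expect_equal(ident[, 1], 1:5, ignore_attr = TRUE)
  expect_equal(ident[, 2], 1:5, ignore_attr = TRUE)

  # enumeration over the 5 gapped alignments of ACD/AD shows (1,1),(3,2)
  # with score 1 is optimal for match 1, mismatch -1, gap -1
  p <- global_sequence_align("ACD", "AD", match = 1, mismatch = -1,
                             gap = -1)
  expect_equal(attr(p, "score"), 1)
  expect_equal(p, rbind(c(1L, 1L), c(3L, 2L)), ignore_attr = TRUE)

  # disjoint alphabets with free gaps: no matched pair scores positive
  q <- global_sequence_align("AAA", "GGG", match = 1, mismatch = -1,
                             gap = 0)
  expect_equal(attr(q, "score"), 0)
  expect_equal(nrow(q), 0)

  set.seed(11)
  for (i in 1:5) {
    sa <- paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = "")
    sb <- paste(sample(c("A", "C", "G", "T"), 9, TRUE), collapse = "")
    ours <- attr(global_sequence_align(sa, sb, 1, -1, -2), "score")
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                    mismatch = -1)
    ref <- Biostrings::pairwiseAlignment(sa, sb, substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2,
                                         scoreOnly = TRUE)
    expect_equal(ours, ref)
  }
})

test_that("Kabsch superposition recovers rigid transforms and rejects degenerate input", {
  set.seed(4)
  pts <- matrix(rnorm(12, sd = 3), 4, 3)
  same <- kabsch_superpose(pts, pts)
  expect_equal(same$rmsd, 0, tolerance = 1e-9)
  expect_equal(same$rotation, diag(3), tolerance = 1e-9)

  shifted <- sweep(pts, 2, c(3, -2, 7), `+`)
  tr <- kabsch_superpose(pts, shifted)
  expect_equal(tr$rmsd, 0, tolerance = 1e-9)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tr$translation, c(3, -2, 7), tolerance = 1e-9)

  Rm <- abfekit:::rotz(0.8) %*%
    matrix(c(1, 0, 0, 0, cos(0.3), -sin(0.3), 0, sin(0.3), cos(0.3)),
           3, 3, byrow = TRUE)
  rotated <- pts %*% t(Rm)
  fit <- kabsch_superpose(pts, rotated)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, Rm, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  expect_error(kabsch_superpose(pts[1:2, ], pts[1:2, ]), "at least 3")
  line <- cbind(1:4, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("superposition RMSD is invariant under common rigid transforms", {
  set.seed(9)
  for (i in 1:10) {
    a <- matrix(rnorm(15, sd = 2), 5, 3)
    b <- a + matrix(rnorm(15, sd = 0.3), 5, 3)
    base <- kabsch_superpose(a, b)$rmsd
    Rm <- abfekit:::random_rotation()
    tv <- rnorm(3, sd = 5)
    a2 <- sweep(a %*% t(Rm), 2, tv, `+`)
    b2 <- sweep(b %*% t(Rm), 2, tv, `+`)
    expect_equal(kabsch_superpose(a2, b2)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("complex alignment transforms protein and ligand into the reference frame", {
  fx <- make_synthetic_complex(5)
  aligned <- align_complex_to_reference(fx$complex, fx$reference)
  ca_a <- aligned$atoms[aligned$atoms$name == "CA" & !aligned$atoms$het, ]
  ca_r <- fx$reference$atoms[fx$reference$atoms$name == "CA", ]
  expect_equal(plain_rmsd(as.matrix(ca_a[, c("x", "y", "z")]),
                          as.matrix(ca_r[, c("x", "y", "z")])), 0,
               tolerance = 1e-6)
  # the ligand must be co-transformed: internal protein-ligand distances
  # are those of the untransformed system
  d_orig <- dist(coords(fx$complex))
  d_new <- dist(coords(aligned))
  expect_equal(as.numeric(d_new), as.numeric(d_orig), tolerance = 1e-6)

  # a point substitution is a mismatch, not a gap: all residues still pair
  mut <- fx$reference
  mut$atoms$resid[mut$atoms$resno == 10] <-
    ifelse(mut$atoms$resid[mut$atoms$resno == 10][1] == "ALA", "GLY", "ALA")
  aligned2 <- align_complex_to_reference(fx$complex, mut)
  expect_equal(attr(aligned2, "n_pairs"), 30)

  lig_only <- new_structure(fx$complex$atoms[fx$complex$atoms$het, ])
  expect_error(align_complex_to_reference(lig_only, fx$reference),
               "Calpha")
})

test_that("symmetry-aware RMSD equals the brute-force minimum over permutations", {
  set.seed(21)
  a <- matrix(rnorm(18), 6, 3)
  expect_equal(symmetry_aware_rmsd(a, a), 0)

  # a phenyl-like ring flipped 180 degrees maps onto itself under its
  # 2-fold automorphism
  ang <- (0:5) * pi / 3
  ring <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  flipped <- ring
  flipped[, 2] <- -flipped[, 2]          # reflection = ring order reversal
  perm <- c(1, 6, 5, 4, 3, 2)
  expect_gt(symmetry_aware_rmsd(ring, flipped), 1)
  expect_equal(symmetry_aware_rmsd(ring, flipped, list(perm)), 0,
               tolerance = 1e-12)

  b <- matrix(rnorm(18), 6, 3)
  perms <- list(sample(6), sample(6), sample(6))
  brute <- min(vapply(c(list(1:6), perms), function(p)
    plain_rmsd(a, b[p, ]), numeric(1)))
  expect_equal(symmetry_aware_rmsd(a, b, perms), brute)
  expect_lte(symmetry_aware_rmsd(a, b, perms), plain_rmsd(a, b))

  expect_error(symmetry_aware_rmsd(a, b, list(1:5)), "permutation")
})

test_that("benzene has the 12 ring automorphisms", {
  perms <- graph_automorphisms(benzene_graph())
  expect_length(perms, 12)
  expect_true(any(vapply(perms, identical, logical(1), 1:6)))
})
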