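# Shared in-code fixtures: tiny PDB/MOL texts and small graphs.

write_tiny_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      10.729   6.768  -4.123  1.00  0.00           C",
    "END"), path)
  path
}

mol_block <- function(natom, nbond, atoms, bonds, title = "fixture") {
  c(title, "  abfekit test", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", natom, nbond),
    atoms, bonds, "M  END", "$$$$")
}

mol_atom_line <- function(x, y, z, el) {
  sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
          x, y, z, el)
}

mol_bond_line <- function(i, j, order = 1) {
  sprintf("%3d%3d%3d  0", i, j, order)
}

write_ethane_mol <- function(path) {
  atoms <- c(
    mol_atom_line(0, 0, 0, "C"), mol_atom_line(1.54, 0, 0, "C"),
    mol_atom_line(-0.4, 1, 0, "H"), mol_atom_line(-0.4, -0.5, 0.87, "H"),
    mol_atom_line(-0.4, -0.5, -0.87, "H"), mol_atom_line(1.94, 1, 0, "H"),
    mol_atom_line(1.94, -0.5, 0.87, "H"),
    mol_atom_line(1.94, -0.5, -0.87, "H"))
  bonds <- c(mol_bond_line(1, 2), mol_bond_line(1, 3), mol_bond_line(1, 4),
             mol_bond_line(1, 5), mol_bond_line(2, 6), mol_bond_line(2, 7),
             mol_bond_line(2, 8))
  writeLines(mol_block(8, 7, atoms, bonds, "ethane"), path)
  path
}

write_benzene_mol <- function(path) {
  ang <- (0:5) * pi / 3
  atoms <- vapply(ang, function(a)
    mol_atom_line(1.4 * cos(a), 1.4 * sin(a), 0, "C"), character(1))
  bonds <- vapply(0:5, function(k)
    mol_bond_line(k + 1, (k + 1) %% 6 + 1, ifelse(k %% 2 == 0, 2, 1)),
    character(1))
  writeLines(mol_block(6, 6, atoms, bonds, "benzene"), path)
  path
}

benzene_graph <- function() {
  molecular_graph(rep("C", 6), cbind(1:6, c(2:6, 1)))
}

butane_graph <- function() {
  # n-butane with explicit hydrogens on the terminal carbons
  molecular_graph(c("C", "C", "C", "C", rep("H", 4)),
                  rbind(c(1, 2), c(2, 3), c(3, 4),
                        c(1, 5), c(1, 6), c(4, 7), c(4, 8)))
}

ethane_graph <- function() {
  molecular_graph(c("C", "C", rep("H", 6)),
                  rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5),
                        c(2, 6), c(2, 7), c(2, 8)))
}

# plain RMSD for oracle comparisons
plain_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# kcal/(mol K) gas constant, duplicated here so tests do not depend on the
# package's internal constant object
R_KCAL_TEST <- 1.98720425864083e-3
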