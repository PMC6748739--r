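# Shared oracles and tiny fixture builders. All expected values here are
# computed independently of the surface engine (closed forms or brute
# force).

# O(n^2) all-pairs neighbour oracle: expanded spheres overlap strictly.
brute_force_neighbors <- function(atoms, probe = 1.4) {
  n <- nrow(atoms)
  rexp <- atoms$radius + probe
  lapply(seq_len(n), function(i) {
    d <- sqrt((atoms$x - atoms$x[i])^2 + (atoms$y - atoms$y[i])^2 +
              (atoms$z - atoms$z[i])^2)
    sort(setdiff(which(d < rexp[i] + rexp), i))
  })
}

# Area of the expanded sphere of atom i.
full_sphere_area <- function(atoms, i, probe = 1.4) {
  4 * pi * (atoms$radius[i] + probe)^2
}

# Minimal hand-written PDB fixture: one ALA (with an altloc pair on CB),
# one DNA residue on chain B, a HETATM ligand, a water, and a hydrogen.
write_mini_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.300   2.400   0.000  1.00  0.00           O",
    "ATOM      5  CB AALA A   1       2.000  -1.000   1.000  0.40  0.00           C",
    "ATOM      6  CB BALA A   1       2.050  -1.050   1.050  0.60  0.00           C",
    "ATOM      7  HA  ALA A   1       1.458   0.500   0.900  1.00  0.00           H",
    "ATOM      8  P    DA B   2       6.000   0.000   0.000  1.00  0.00           P",
    "ATOM      9  C1'  DA B   2       7.200   1.000   0.000  1.00  0.00           C",
    "ATOM     10  N9   DA B   2       8.000   2.000   0.000  1.00  0.00           N",
    "HETATM   11  C1  LIG C   5       4.000   4.000   4.000  1.00  0.00           C",
    "HETATM   12  O   HOH D   9      10.000  10.000  10.000  1.00  0.00           O",
    "END"), path)
  path
}

write_mini_mol2 <- function(path) {
  writeLines(c(
    "@<TRIPOS>MOLECULE",
    "toy",
    " 3 2 1",
    "SMALL",
    "NO_CHARGES",
    "@<TRIPOS>ATOM",
    "  1 C1   0.000  0.000  0.000 C.3  1 LIG1  0.0",
    "  2 O1   1.430  0.000  0.000 O.2  1 LIG1  0.0",
    "  3 H1  -0.500  0.900  0.000 H    1 LIG1  0.0",
    "@<TRIPOS>BOND",
    "  1 1 2 2",
    "  2 1 3 1"), path)
  path
}

# Two staggered rows of atoms: overlaps exist only across objects (intra-
# object spacing 7 A exceeds the 6 A pair cutoff at r = 1.6, probe = 1.4),
# and most atoms have two cross-object occluders.
make_cross_only_rows <- function() {
  x1 <- c(0, 7, 14); x2 <- c(2, 9, 16)
  atoms <- data.frame(
    serial = 1:6, name = paste0("C", 1:6), element = "C", resname = "UNK",
    chain = rep(c("A", "B"), each = 3), resno = rep(1:3, 2), inscode = "",
    x = c(x1, x2), y = rep(c(0, 2.5), each = 3), z = 0,
    occupancy = 1, altloc = "", hetero = FALSE, stringsAsFactors = FALSE)
  atoms$radius <- 1.6
  atoms$object <- rep(1:2, each = 3)
  attr(atoms, "probe") <- 1.4
  attr(atoms, "format") <- "synthetic"
  atoms
}
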