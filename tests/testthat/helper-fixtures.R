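# Shared fixtures, all built in code at test time.

# Hand-written PDB text for a tiny system: n protein glycine C-alphas on the
# x axis plus an optional HETATM ligand carbon.
write_tiny_pdb <- function(path, n_res = 3, ligand = FALSE) {
  fmt <- "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  lines <- vapply(seq_len(n_res), function(i) {
    sprintf(fmt, "ATOM", i, " CA ", "", "GLY", "A", i, "",
            i * 1.5, 0.25 * i, -1.0, 1, 0, "C")
  }, character(1))
  if (ligand) {
    lines <- c(lines, sprintf(fmt, "HETATM", n_res + 1L, " C1 ", "", "LIG",
                              "A", 900L, "", 0, 5, 5, 1, 0, "C"))
  }
  writeLines(c(lines, "END"), path)
  path
}

# Two-residue structure with nearest sidechain heavy atoms at a chosen
# distance (leucine CD1 vs alanine CB).
two_residue_structure <- function(gap = 3.30) {
  atoms <- data.frame(
    serial = 1:5,
    name = c("CA", "CB", "CD1", "CA", "CB"),
    element = "C",
    resno = c(1L, 1L, 1L, 2L, 2L),
    resname = c("LEU", "LEU", "LEU", "ALA", "ALA"),
    chain = "A", is_ligand = FALSE, stringsAsFactors = FALSE)
  xyz <- rbind(c(-4, 0, 0), c(-2, 0, 0), c(0, 0, 0),
               c(gap + 3, 0, 0), c(gap, 0, 0))
  colnames(xyz) <- c("x", "y", "z")
  structure(list(atoms = atoms, xyz = xyz, source = "fixture"),
            class = "mol_structure")
}

# One-frame ensemble around a structure.
single_frame_ensemble <- function(struct, frame_interval_ns = 1) {
  arr <- array(0, dim = c(1L, nrow(struct$atoms), 3L))
  arr[1, , ] <- struct$xyz
  trajectory_ensemble(struct, list(arr), frame_interval_ns)
}

# 4-state metastable chain: two 2-state blocks, intra-block probability
# 0.95 (split evenly), inter-block 0.05 (split evenly). Second eigenvalue of
# the block-membership mode is 0.9.
metastable4 <- function() {
  matrix(c(.475, .475, .025, .025,
           .475, .475, .025, .025,
           .025, .025, .475, .475,
           .025, .025, .475, .475), 4, byrow = TRUE)
}

# 3-state reversible chain whose middle state has P(I->A) = 0.2 and
# P(I->B) = 0.1: committor q(I) = 1/3 by first-step analysis.
chain3 <- function() {
  matrix(c(.8, .2, 0,
           .2, .7, .1,
           0, .3, .7), 3, byrow = TRUE)
}

macro_members_test <- function(mc, M) mc$active[mc$assignment == M]

expect_region <- function(d, r, label, ...) {
  st <- data.frame(tm6_distance = d, npxxy_rmsd = r)
  expect_identical(classify_region(st, ...), label)
}
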