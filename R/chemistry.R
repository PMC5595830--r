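# Residue chemistry tables used for sidechain selection, hydrogen-bond
# donors/acceptors, charges and aromatic rings. Atom names follow PDB v3
# conventions.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT", "H", "HA", "HA2", "HA3",
                    "H1", "H2", "H3", "HN")

AMINO_ACIDS <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

AROMATIC_RINGS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "NE1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

SIDECHAIN_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
  ASN = "ND2", GLN = "NE2", LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"), TRP = "NE1"
)

SIDECHAIN_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH",
  HIS = c("ND1", "NE2"), MET = "SD"
)

POSITIVE_SIDECHAIN <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2")
)

NEGATIVE_SIDECHAIN <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")
)

# Sidechain atom indices for a residue; glycine has no sidechain heavy atoms
# and is represented by its C-alpha.
sidechain_indices <- function(struct, resno, heavy_only = TRUE) {
  a <- struct$atoms
  sel <- a$resno == resno & !a$is_ligand & !(a$name %in% BACKBONE_ATOMS)
  if (heavy_only) sel <- sel & a$element != "H"
  idx <- which(sel)
  if (length(idx) == 0L) idx <- atom_indices(struct, resno, names = "CA")
  idx
}

# Non-polar (carbon/sulfur) sidechain atoms, excluding aromatic-ring atoms:
# atom typing is disjoint so aromatic carbons contribute to the aromatic
# fingerprint bits rather than the apolar one.
apolar_sidechain_indices <- function(struct, resno) {
  a <- struct$atoms
  idx <- sidechain_indices(struct, resno)
  resname <- a$resname[idx[1]]
  ring <- AROMATIC_RINGS[[resname]]
  keep <- a$element[idx] %in% c("C", "S")
  if (!is.null(ring)) keep <- keep & !(a$name[idx] %in% ring)
  idx[keep]
}

named_atom_indices <- function(struct, resno, names) {
  a <- struct$atoms
  which(a$resno == resno & !a$is_ligand & a$name %in% names)
}

# Hydrogens bonded to a heavy atom, identified geometrically (<= 1.3 A).
attached_hydrogens <- function(struct, heavy_idx, xyz = struct$xyz) {
  a <- struct$atoms
  res <- a$resno[heavy_idx]
  hs <- which(a$resno == res & a$element == "H" &
                a$is_ligand == a$is_ligand[heavy_idx])
  if (length(hs) == 0L) return(integer(0))
  d <- row_norms(xyz[hs, , drop = FALSE] -
                   matrix(xyz[heavy_idx, ], length(hs), 3, byrow = TRUE))
  hs[d <= 1.3]
}
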