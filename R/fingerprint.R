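# 7-bit structural interaction fingerprint: per-residue binary encoding of
# the ligand-contact mode. Bit order: apolar, aromatic face-to-face, aromatic
# edge-to-face, H-bond (protein donor), H-bond (protein acceptor),
# electrostatic (positive protein residue), electrostatic (negative protein
# residue). Only sidechain atoms are considered.

FP_BITS <- c("apolar", "aromatic_f2f", "aromatic_e2f", "hbond_donor",
             "hbond_acceptor", "electro_pos", "electro_neg")

# Least-squares plane normal of a ring (unit vector).
ring_normal <- function(coords) {
  c0 <- sweep(coords, 2, colMeans(coords))
  n <- svd(c0)$v[, 3]
  n / sqrt(sum(n^2))
}

default_ligand_types <- function(struct) {
  a <- struct$atoms
  lig <- which(a$is_ligand)
  rings <- attr(struct, "ligand_rings")
  if (is.null(rings)) rings <- list()
  ring_atoms <- unlist(rings)
  nm <- a$name[lig]; el <- a$element[lig]
  list(
    apolar = lig[el %in% c("C", "S") & !(nm %in% ring_atoms)],
    donor = lig[el == "N"],
    acceptor = lig[el == "O"],
    positive = lig[el == "N"],
    negative = lig[el == "O"],
    rings = lapply(rings, function(r) lig[match(r, nm)])
  )
}

#' Compute the 7-bit protein-ligand interaction fingerprint
#'
#' For each protein residue, seven binary flags describing its interaction
#' with the ligand: apolar contact between non-polar atoms (< 4.5 A),
#' aromatic face-to-face and edge-to-face stacking (ring centroids <= 4 A;
#' interplanar angle <= 30 deg or in 60-120 deg), hydrogen bonds with the
#' protein as donor or acceptor (heavy-atom distance <= 3.5 A, D-H...A angle
#' >= 120 deg when hydrogens are present), and electrostatic contacts of
#' charged protein sidechains with oppositely typed ligand atoms (< 4 A).
#' Aromatic-ring carbons are typed aromatic, not apolar, so the bit classes
#' are disjoint.
#'
#' Ligand atom typing defaults to element-based rules (C/S not in a declared
#' ring: apolar; N: donor and cation candidate; O: acceptor and anion
#' candidate); declare ligand rings via the `ligand_rings` attribute of the
#' structure (set by [build_toy_complex()]) or override everything with
#' `ligand_types`.
#'
#' @param struct A `mol_structure` containing flagged ligand atoms.
#' @param ligand_types Optional list with integer atom-index vectors
#'   `apolar`, `donor`, `acceptor`, `positive`, `negative` and a list `rings`.
#' @param cutoffs Named list overriding `apolar` (4.5), `aromatic` (4),
#'   `electro` (4), `hbond` (3.5), `hbond_angle` (120), `f2f_angle` (30),
#'   `e2f_angle` (c(60, 120)).
#' @return Integer matrix `n_residues x 7` (rownames: residue numbers,
#'   colnames: bit names).
#' @export
compute_fingerprint <- function(struct, ligand_types = NULL, cutoffs = list()) {
  cut <- utils::modifyList(list(apolar = 4.5, aromatic = 4, electro = 4,
                                hbond = 3.5, hbond_angle = 120,
                                f2f_angle = 30, e2f_angle = c(60, 120)),
                           cutoffs)
  a <- struct$atoms
  xyz <- struct$xyz
  if (!any(a$is_ligand)) stopf("structure contains no ligand atoms")
  lt <- if (is.null(ligand_types)) default_ligand_types(struct) else ligand_types
  resnos <- protein_residues(struct)
  fp <- matrix(0L, length(resnos), length(FP_BITS),
               dimnames = list(resnos, FP_BITS))
  lig_ring_data <- lapply(lt$rings, function(idx) {
    coords <- xyz[idx, , drop = FALSE]
    list(centroid = colMeans(coords), normal = ring_normal(coords))
  })
  gmin <- function(ia, ib) {
    if (length(ia) == 0L || length(ib) == 0L) return(Inf)
    min_cross_dist(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  }
  for (i in seq_along(resnos)) {
    r <- resnos[i]
    rn <- a$resname[a$resno == r & !a$is_ligand][1]
    if (!(rn %in% AMINO_ACIDS)) {
      warnf("unknown residue type '%s' at residue %d; fingerprint left zero", rn, r)
      next
    }
    # apolar
    if (gmin(apolar_sidechain_indices(struct, r), lt$apolar) < cut$apolar) {
      fp[i, "apolar"] <- 1L
    }
    # aromatic stacking
    ring_names <- AROMATIC_RINGS[[rn]]
    if (!is.null(ring_names) && length(lig_ring_data) > 0) {
      pidx <- named_atom_indices(struct, r, ring_names)
      if (length(pidx) >= 5) {
        pc <- xyz[pidx, , drop = FALSE]
        pcen <- colMeans(pc); pnorm <- ring_normal(pc)
        for (lr in lig_ring_data) {
          if (vec_dist(pcen, lr$centroid) > cut$aromatic) next
          ang <- acos(min(1, abs(sum(pnorm * lr$normal)))) * 180 / pi
          if (ang <= cut$f2f_angle) fp[i, "aromatic_f2f"] <- 1L
          if (ang >= cut$e2f_angle[1] && ang <= cut$e2f_angle[2]) {
            fp[i, "aromatic_e2f"] <- 1L
          }
        }
      }
    }
    # hydrogen bonds (geometric criterion shared with detect_hbond)
    hb <- function(donors, acceptors) {
      for (di in donors) {
        hs <- attached_hydrogens(struct, di)
        for (ai in acceptors) {
          if (vec_dist(xyz[di, ], xyz[ai, ]) > cut$hbond) next
          if (length(hs) == 0L) return(TRUE)
          for (h in hs) {
            v1 <- xyz[di, ] - xyz[h, ]; v2 <- xyz[ai, ] - xyz[h, ]
            ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                      sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
            if (ang >= cut$hbond_angle) return(TRUE)
          }
        }
      }
      FALSE
    }
    dn <- SIDECHAIN_DONORS[[rn]]
    if (!is.null(dn) &&
        hb(named_atom_indices(struct, r, dn), lt$acceptor)) {
      fp[i, "hbond_donor"] <- 1L
    }
    ac <- SIDECHAIN_ACCEPTORS[[rn]]
    if (!is.null(ac) && hb(lt$donor, named_atom_indices(struct, r, ac))) {
      fp[i, "hbond_acceptor"] <- 1L
    }
    # electrostatics
    pos <- POSITIVE_SIDECHAIN[[rn]]
    if (!is.null(pos) &&
        gmin(named_atom_indices(struct, r, pos), lt$negative) < cut$electro) {
      fp[i, "electro_pos"] <- 1L
    }
    neg <- NEGATIVE_SIDECHAIN[[rn]]
    if (!is.null(neg) &&
        gmin(named_atom_indices(struct, r, neg), lt$positive) < cut$electro) {
      fp[i, "electro_neg"] <- 1L
    }
  }
  fp
}

#' Write fingerprints as CSV
#'
#' @param fp Matrix from [compute_fingerprint()].
#' @param path Output CSV path.
#' @export
write_fingerprint_csv <- function(fp, path) {
  df <- data.frame(resno = as.integer(rownames(fp)), fp, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
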