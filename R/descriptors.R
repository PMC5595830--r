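# Structural descriptor sets and featurization: C-alpha pair distances,
# sidechain-sidechain contacts, residue-ligand contacts, and the order
# parameters used to characterize activation (TM3-TM6 distance, NPxxY-segment
# RMSD, hydrogen bonds).

#' Build a structural descriptor set
#'
#' Assembles the three descriptor families used to featurize receptor
#' trajectories: (1) all unordered C-alpha pair distances over a thinned
#' residue selection; (2) binary sidechain-sidechain contacts for every
#' residue pair whose minimum sidechain heavy-atom distance is below
#' `contact_cutoff` in at least one reference structure; (3) binary
#' residue-ligand contacts, one per residue of `ligand_range`.
#'
#' @param topology A `mol_structure`.
#' @param selection Residue numbers for the pair-distance family (e.g. from
#'   [select_every_kth()]).
#' @param references List of `mol_structure` reference structures (e.g. the
#'   inactive and activated crystal structures) used to discover contact
#'   pairs; `NULL` skips the sidechain-contact family.
#' @param ligand_range Length-2 integer vector giving the residue interval
#'   that receives one ligand-contact descriptor each; `NULL` skips the
#'   family.
#' @param contact_cutoff Sidechain contact cutoff in Angstrom (default 7).
#' @param ligand_cutoff Residue-ligand heavy-atom contact cutoff (default 7).
#' @return A data frame of class `descriptor_set` with columns `kind`
#'   (`ca_pair_distance`, `sidechain_contact`, `ligand_contact`), `res_a`,
#'   `res_b` (NA for ligand contacts), `cutoff` and `name`.
#' @export
build_descriptor_set <- function(topology, selection, references = NULL,
                                 ligand_range = NULL, contact_cutoff = 7,
                                 ligand_cutoff = 7) {
  if (length(selection) == 0L) stopf("selection is empty")
  out <- list()
  pairs <- which(upper.tri(matrix(0, length(selection), length(selection))),
                 arr.ind = TRUE)
  if (nrow(pairs) > 0) {
    out$ca <- data.frame(
      kind = "ca_pair_distance",
      res_a = selection[pairs[, 1]], res_b = selection[pairs[, 2]],
      cutoff = NA_real_, stringsAsFactors = FALSE)
  }
  if (!is.null(references)) {
    if (inherits(references, "mol_structure")) references <- list(references)
    resids <- protein_residues(topology)
    for (ref in references) {
      missing <- setdiff(resids, protein_residues(ref))
      if (length(missing)) {
        stopf("reference structure lacks residues: %s",
              paste(utils::head(missing, 5), collapse = ", "))
      }
    }
    hit <- matrix(FALSE, length(resids), length(resids))
    for (ref in references) {
      sc <- lapply(resids, function(r) {
        ref$xyz[sidechain_indices(ref, r), , drop = FALSE]
      })
      for (i in seq_along(resids)) {
        for (j in seq_along(resids)) {
          if (j <= i || hit[i, j]) next
          if (min_cross_dist(sc[[i]], sc[[j]]) < contact_cutoff) {
            hit[i, j] <- TRUE
          }
        }
      }
    }
    ij <- which(hit, arr.ind = TRUE)
    if (nrow(ij) > 0) {
      out$sc <- data.frame(
        kind = "sidechain_contact",
        res_a = resids[ij[, 1]], res_b = resids[ij[, 2]],
        cutoff = contact_cutoff, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(ligand_range)) {
    lr <- seq.int(ligand_range[1], ligand_range[2])
    out$lig <- data.frame(
      kind = "ligand_contact", res_a = lr, res_b = NA_integer_,
      cutoff = ligand_cutoff, stringsAsFactors = FALSE)
  }
  ds <- do.call(rbind, out)
  rownames(ds) <- NULL
  ds$name <- ifelse(ds$kind == "ca_pair_distance",
                    sprintf("ca_%d_%d", ds$res_a, ds$res_b),
             ifelse(ds$kind == "sidechain_contact",
                    sprintf("sc_%d_%d", ds$res_a, ds$res_b),
                    sprintf("lig_%d", ds$res_a)))
  if (anyDuplicated(ds$name)) stopf("duplicate descriptor definitions")
  class(ds) <- c("descriptor_set", class(ds))
  ds
}

#' @export
print.descriptor_set <- function(x, ...) {
  tab <- table(x$kind)
  cat("descriptor_set:", nrow(x), "descriptors (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")\n")
  invisible(x)
}

# Distance between two atom groups in every frame of one trajectory array.
frame_group_min_dist <- function(arr, ia, ib) {
  nf <- dim(arr)[1]
  best <- rep(Inf, nf)
  for (i in ia) {
    for (j in ib) {
      d <- sqrt((arr[, i, 1] - arr[, j, 1])^2 +
                  (arr[, i, 2] - arr[, j, 2])^2 +
                  (arr[, i, 3] - arr[, j, 3])^2)
      best <- pmin(best, d)
    }
  }
  best
}

#' Compute a feature matrix from a trajectory ensemble
#'
#' Evaluates every descriptor in every frame. Pair-distance descriptors give
#' distances in Angstrom; contact descriptors give 1 when the minimum
#' relevant heavy-atom distance is strictly below the cutoff, else 0.
#'
#' @param traj A `traj_ensemble`.
#' @param descriptors A `descriptor_set`.
#' @return An object of class `feature_set`: list with `values` (one
#'   `n_frames x n_descriptors` matrix per trajectory), `descriptors`, and
#'   `frame_interval_ns`.
#' @export
compute_features <- function(traj, descriptors) {
  topo <- traj$topology
  lig_idx <- which(topo$atoms$is_ligand & topo$atoms$element != "H")
  groups_a <- vector("list", nrow(descriptors))
  groups_b <- vector("list", nrow(descriptors))
  for (d in seq_len(nrow(descriptors))) {
    kind <- descriptors$kind[d]
    ra <- descriptors$res_a[d]
    if (kind == "ca_pair_distance") {
      ia <- atom_indices(topo, ra, names = "CA")
      ib <- atom_indices(topo, descriptors$res_b[d], names = "CA")
    } else if (kind == "sidechain_contact") {
      ia <- sidechain_indices(topo, ra)
      ib <- sidechain_indices(topo, descriptors$res_b[d])
    } else {
      a <- topo$atoms
      ia <- which(a$resno == ra & !a$is_ligand & a$element != "H")
      ib <- lig_idx
    }
    if (length(ia) == 0L || length(ib) == 0L) {
      stopf("missing atoms for descriptor '%s'", descriptors$name[d])
    }
    groups_a[[d]] <- ia; groups_b[[d]] <- ib
  }
  values <- lapply(traj$frames, function(arr) {
    m <- matrix(0, dim(arr)[1], nrow(descriptors))
    colnames(m) <- descriptors$name
    for (d in seq_len(nrow(descriptors))) {
      dist <- frame_group_min_dist(arr, groups_a[[d]], groups_b[[d]])
      m[, d] <- if (descriptors$kind[d] == "ca_pair_distance") dist
                else as.numeric(dist < descriptors$cutoff[d])
    }
    m
  })
  structure(list(values = values, descriptors = descriptors,
                 frame_interval_ns = traj$frame_interval_ns),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set: %d trajectories, %d descriptors, %d frames total\n",
              length(x$values), nrow(x$descriptors),
              sum(vapply(x$values, nrow, integer(1)))))
  invisible(x)
}

# Per-frame scalar order parameter over an ensemble.
op_trace <- function(values, name, units) {
  structure(list(values = values, name = name, units = units),
            class = "op_trace")
}

#' @export
print.op_trace <- function(x, ...) {
  v <- unlist(x$values)
  cat(sprintf("op_trace '%s' (%s): %d frames, range [%.3g, %.3g]\n",
              x$name, x$units, length(v), min(v), max(v)))
  invisible(x)
}

as_ensemble <- function(x) {
  if (inherits(x, "traj_ensemble")) return(x)
  if (inherits(x, "mol_structure")) {
    arr <- array(0, dim = c(1L, nrow(x$atoms), 3L))
    arr[1, , ] <- x$xyz
    return(trajectory_ensemble(x, list(arr), 1))
  }
  stopf("expected a traj_ensemble or mol_structure")
}

#' Per-frame distance between two residues
#'
#' @param x A `traj_ensemble`, or a single `mol_structure` (in which case a
#'   scalar is returned).
#' @param res_a,res_b Residue numbers.
#' @param mode `"ca"` (C-alpha distance), `"min_sidechain"` (minimum
#'   sidechain heavy-atom distance; glycine is represented by its C-alpha) or
#'   `"min_heavy"` (minimum over all heavy atoms).
#' @return An `op_trace` (Angstrom), or a numeric scalar for structure input.
#' @export
pair_distance <- function(x, res_a, res_b,
                          mode = c("ca", "min_sidechain", "min_heavy")) {
  mode <- match.arg(mode)
  single <- inherits(x, "mol_structure")
  ens <- as_ensemble(x)
  topo <- ens$topology
  pick <- function(r) {
    idx <- switch(mode,
      ca = atom_indices(topo, r, names = "CA"),
      min_sidechain = sidechain_indices(topo, r),
      min_heavy = which(topo$atoms$resno == r & !topo$atoms$is_ligand &
                          topo$atoms$element != "H"))
    if (length(idx) == 0L) stopf("residue %d has no atoms for mode '%s'", r, mode)
    idx
  }
  ia <- pick(res_a); ib <- pick(res_b)
  vals <- lapply(ens$frames, frame_group_min_dist, ia = ia, ib = ib)
  if (single) return(vals[[1]][1])
  op_trace(vals, sprintf("dist_%s_%d_%d", mode, res_a, res_b), "angstrom")
}

# Kabsch optimal rotation: returns mobile coordinates superposed onto fixed.
kabsch_superpose <- function(mobile, fixed, mobile_fit, fixed_fit) {
  mf <- mobile[mobile_fit, , drop = FALSE]
  ff <- fixed[fixed_fit, , drop = FALSE]
  cm <- colMeans(mf); cf <- colMeans(ff)
  H <- crossprod(sweep(mf, 2, cm), sweep(ff, 2, cf))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(sweep(mobile, 2, cm) %*% t(R), 2, cf, "+")
}

#' Segment C-alpha RMSD from a reference structure
#'
#' For each frame: rigid-body superposition of the frame onto the reference
#' over the C-alpha atoms of `fit_selection`, then RMSD over the C-alpha
#' atoms of `segment` without refitting. This measures local backbone
#' distortion (e.g. of the NPxxY motif) in the frame of the whole receptor.
#'
#' @param traj A `traj_ensemble`.
#' @param reference A `mol_structure` (e.g. the inactive crystal structure).
#' @param segment Length-2 residue interval measured by the RMSD.
#' @param fit_selection Residues used for the superposition; default all
#'   protein residues common to trajectory topology and reference.
#' @return An `op_trace` in Angstrom.
#' @export
segment_rmsd <- function(traj, reference, segment, fit_selection = NULL) {
  topo <- traj$topology
  seg_res <- seq.int(segment[1], segment[2])
  if (length(seg_res) == 0L) stopf("empty segment")
  common <- intersect(protein_residues(topo), protein_residues(reference))
  if (is.null(fit_selection)) fit_selection <- common
  if (!all(fit_selection %in% common)) {
    stopf("fit_selection residues missing from trajectory topology or reference")
  }
  if (!all(seg_res %in% common)) stopf("segment residues missing from topology or reference")
  ca_of <- function(struct, res) {
    idx <- vapply(res, function(r) {
      i <- atom_indices(struct, r, names = "CA")
      if (length(i) == 0L) stopf("residue %d lacks a C-alpha atom", r)
      i[1]
    }, integer(1))
    idx
  }
  fit_m <- ca_of(topo, fit_selection); fit_f <- ca_of(reference, fit_selection)
  seg_m <- ca_of(topo, seg_res); seg_f <- ca_of(reference, seg_res)
  ref_xyz <- reference$xyz
  vals <- lapply(traj$frames, function(arr) {
    nf <- dim(arr)[1]
    out <- numeric(nf)
    for (f in seq_len(nf)) {
      xyz <- matrix(arr[f, , ], ncol = 3)
      sup <- kabsch_superpose(xyz, ref_xyz, fit_m, fit_f)
      diff <- sup[seg_m, , drop = FALSE] - ref_xyz[seg_f, , drop = FALSE]
      out[f] <- sqrt(mean(rowSums(diff^2)))
    }
    out
  })
  op_trace(vals, sprintf("rmsd_%d_%d", segment[1], segment[2]), "angstrom")
}

#' Detect a sidechain hydrogen bond per frame
#'
#' Geometric criterion: donor-acceptor heavy-atom distance <= 3.5 A and, when
#' explicit hydrogens bonded to the donor are present, a D-H...A angle of at
#' least 120 degrees; distance-only when hydrogens are absent.
#'
#' @param traj A `traj_ensemble` (or `mol_structure`).
#' @param donor_res Residue providing the donor heavy atom.
#' @param acceptor_res Residue providing the acceptor heavy atom.
#' @param dist_cutoff,angle_cutoff Criterion parameters (A, degrees).
#' @return Binary `op_trace` (or scalar for structure input).
#' @export
detect_hbond <- function(traj, donor_res, acceptor_res, dist_cutoff = 3.5,
                         angle_cutoff = 120) {
  single <- inherits(traj, "mol_structure")
  ens <- as_ensemble(traj)
  topo <- ens$topology
  a <- topo$atoms
  polar_sidechain <- function(r, table) {
    rn <- a$resname[a$resno == r & !a$is_ligand][1]
    names <- table[[rn]]
    idx <- if (!is.null(names)) named_atom_indices(topo, r, names) else integer(0)
    if (length(idx) == 0L) {
      sc <- sidechain_indices(topo, r)
      idx <- sc[a$element[sc] %in% c("N", "O", "S")]
    }
    idx
  }
  don <- polar_sidechain(donor_res, SIDECHAIN_DONORS)
  acc <- polar_sidechain(acceptor_res, SIDECHAIN_ACCEPTORS)
  if (length(don) == 0L) stopf("residue %d has no donor-capable sidechain atom", donor_res)
  if (length(acc) == 0L) stopf("residue %d has no acceptor-capable sidechain atom", acceptor_res)
  vals <- lapply(ens$frames, function(arr) {
    nf <- dim(arr)[1]
    out <- integer(nf)
    for (f in seq_len(nf)) {
      xyz <- matrix(arr[f, , ], ncol = 3)
      hit <- FALSE
      for (di in don) {
        hs <- attached_hydrogens(topo, di, xyz)
        for (ai in acc) {
          if (vec_dist(xyz[di, ], xyz[ai, ]) > dist_cutoff) next
          if (length(hs) == 0L) { hit <- TRUE; break }
          for (h in hs) {
            v1 <- xyz[di, ] - xyz[h, ]
            v2 <- xyz[ai, ] - xyz[h, ]
            ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                      sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
            if (ang >= angle_cutoff) { hit <- TRUE; break }
          }
          if (hit) break
        }
        if (hit) break
      }
      out[f] <- as.integer(hit)
    }
    out
  })
  if (single) return(vals[[1]][1])
  op_trace(vals, sprintf("hbond_%d_%d", donor_res, acceptor_res), "binary")
}
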