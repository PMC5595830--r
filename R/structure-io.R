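# Structure and trajectory input, residue selections, and the array
# container used to persist intermediate matrices.

# Residue names excluded from ligand detection: solvent, common ions, and
# membrane components that appear as HETATM records but are not the ligand.
DEFAULT_LIGAND_EXCLUDE <- c("HOH", "TIP3", "WAT", "SOL", "NA", "SOD", "CL",
                            "CLA", "K", "POT", "MG", "ZN", "POPC", "CHL1",
                            "CLR")

#' Read a molecular structure from a PDB file
#'
#' Parses ATOM/HETATM records into a light-weight structure object. HETATM
#' atoms whose residue name is not in `ligand_exclude` are flagged as ligand
#' atoms; waters, ions and membrane lipids are excluded from that flag by
#' default.
#'
#' @param path Path to a PDB file.
#' @param ligand_exclude Character vector of HETATM residue names that are
#'   never treated as the ligand (solvent, ions, lipids).
#' @return An object of class `mol_structure`: a list with `atoms` (data frame
#'   with columns serial, name, element, resno, resname, chain, is_ligand) and
#'   `xyz` (numeric n x 3 matrix, Angstrom).
#' @examples
#' pdb <- system.file("extdata", "toy_dimer.pdb", package = "kinflow")
#' s <- read_structure(pdb)
#' nrow(s$atoms)
#' @export
read_structure <- function(path, ligand_exclude = DEFAULT_LIGAND_EXCLUDE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") | substr(lines, 1, 4) == "ATOM" |
    substr(lines, 1, 6) == "HETATM"
  idx <- which(is_atom)
  if (length(idx) == 0L) stopf("no ATOM/HETATM records in %s", path)
  # Pre-scan coordinate fields so a malformed record is reported by line.
  for (i in idx) {
    coords <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                            substr(lines[i], 39, 46),
                                            substr(lines[i], 47, 54))))
    if (any(is.na(coords))) {
      stopf("malformed ATOM/HETATM record at line %d of %s", i, path)
    }
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  element <- at$elesy
  if (is.null(element)) element <- ""
  element <- trimws(element)
  # Fall back to the first letter of the atom name where the element column
  # is absent (common in hand-written or minimized PDB files).
  miss <- is.na(element) | element == ""
  if (any(miss)) {
    nm <- trimws(at$elety[miss])
    element[miss] <- substr(gsub("^[0-9]+", "", nm), 1, 1)
  }
  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = toupper(element),
    resno = at$resno,
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    is_ligand = at$type == "HETATM" & !(trimws(at$resid) %in% ligand_exclude),
    stringsAsFactors = FALSE
  )
  xyz <- cbind(at$x, at$y, at$z)
  colnames(xyz) <- c("x", "y", "z")
  if (any(!is.finite(xyz))) stopf("non-finite coordinates in %s", path)
  if (anyDuplicated(atoms$serial)) {
    warnf("duplicate atom serials in %s; records kept in file order", path)
  }
  structure(list(atoms = atoms, xyz = xyz, source = path),
            class = "mol_structure")
}

#' @export
print.mol_structure <- function(x, ...) {
  prot <- !x$atoms$is_ligand
  cat(sprintf("mol_structure: %d atoms (%d ligand), %d residues\n",
              nrow(x$atoms), sum(x$atoms$is_ligand),
              length(unique(x$atoms$resno[prot]))))
  invisible(x)
}

# Indices of atoms belonging to residue `resno` (protein side by default).
atom_indices <- function(struct, resno, names = NULL, ligand = FALSE) {
  a <- struct$atoms
  sel <- a$resno == resno & a$is_ligand == ligand
  if (!is.null(names)) sel <- sel & a$name %in% names
  which(sel)
}

protein_residues <- function(struct) {
  sort(unique(struct$atoms$resno[!struct$atoms$is_ligand]))
}

#' Select every k-th residue in a range
#'
#' Returns residues `start_res, start_res + k, ...` up to `end_res`, the
#' uniform thinning used to keep the C-alpha pair-distance descriptor set
#' tractable (e.g. one in every three residues between S64 and I352 of the
#' receptor gives 97 residues).
#'
#' @param topology A `mol_structure`.
#' @param start_res,end_res First and last residue number of the range.
#' @param k Stride (1 keeps every residue).
#' @return Sorted integer vector of residue numbers.
#' @export
select_every_kth <- function(topology, start_res, end_res, k = 1L) {
  if (!is_count(k)) stopf("k must be a positive integer")
  if (start_res > end_res) stopf("start_res must be <= end_res")
  sel <- seq.int(start_res, end_res, by = k)
  present <- protein_residues(topology)
  missing <- setdiff(sel, present)
  if (length(missing) == length(sel)) stopf("selection is empty: no residues in range present in topology")
  if (length(missing) > 0) {
    stopf("residues absent from topology: %s",
          paste(utils::head(missing, 10), collapse = ", "))
  }
  as.integer(sel)
}

#' Assemble a trajectory ensemble
#'
#' Wraps per-trajectory coordinate arrays with a shared topology and frame
#' interval. Used directly by the synthetic generators; file input goes
#' through [read_trajectory()].
#'
#' @param topology A `mol_structure` shared by all trajectories.
#' @param frames List of numeric arrays, each `n_frames x n_atoms x 3` (A).
#' @param frame_interval_ns Time between stored frames in nanoseconds.
#' @return An object of class `traj_ensemble`.
#' @export
trajectory_ensemble <- function(topology, frames, frame_interval_ns) {
  if (!inherits(topology, "mol_structure")) stopf("topology must be a mol_structure")
  if (!is.list(frames) || length(frames) == 0L) stopf("frames must be a non-empty list")
  if (!is.numeric(frame_interval_ns) || frame_interval_ns <= 0) {
    stopf("frame_interval_ns must be positive")
  }
  nat <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    d <- dim(frames[[i]])
    if (length(d) != 3L || d[2] != nat || d[3] != 3L || d[1] < 1L) {
      stopf("trajectory %d: expected n_frames x %d x 3 array", i, nat)
    }
    if (any(!is.finite(frames[[i]]))) stopf("trajectory %d has non-finite coordinates", i)
  }
  structure(list(topology = topology, frames = frames,
                 frame_interval_ns = frame_interval_ns),
            class = "traj_ensemble")
}

#' @export
print.traj_ensemble <- function(x, ...) {
  nf <- vapply(x$frames, function(f) dim(f)[1], integer(1))
  cat(sprintf("traj_ensemble: %d trajectories, %d frames total, %g ns/frame\n",
              length(x$frames), sum(nf), x$frame_interval_ns))
  invisible(x)
}

n_frames <- function(traj) vapply(traj$frames, function(f) dim(f)[1], integer(1))

#' Read trajectory coordinate files
#'
#' Reads one trajectory per file and assembles them, in the given order, into
#' a [trajectory_ensemble()]. DCD files are read with bio3d; multi-model PDB
#' files are also accepted. XTC is not supported by any installed reader and
#' raises an error advising conversion to DCD.
#'
#' @param paths Character vector of coordinate file paths (.dcd or .pdb).
#' @param topology A `mol_structure`; atom counts must match every file.
#' @param frame_interval_ns Time between stored frames in nanoseconds.
#' @return A `traj_ensemble` with one element per input file.
#' @export
read_trajectory <- function(paths, topology, frame_interval_ns) {
  if (length(paths) == 0L) stopf("no trajectory files given")
  nat <- nrow(topology$atoms)
  frames <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    if (!file.exists(p)) stopf("file not found: %s", p)
    ext <- tolower(tools::file_ext(p))
    if (ext == "xtc") {
      stopf("XTC reading is not supported; convert %s to DCD first", p)
    }
    xyz <- if (ext == "dcd") {
      unclass(bio3d::read.dcd(p, verbose = FALSE))
    } else if (ext %in% c("pdb", "ent")) {
      unclass(bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)$xyz)
    } else {
      stopf("unsupported trajectory format '%s' (%s); use DCD or PDB", ext, p)
    }
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    if (ncol(xyz) != 3L * nat) {
      stopf("%s: %d atoms per frame but topology has %d", p, ncol(xyz) / 3, nat)
    }
    arr <- array(0, dim = c(nrow(xyz), nat, 3L))
    arr[, , 1] <- xyz[, seq(1, 3 * nat, by = 3), drop = FALSE]
    arr[, , 2] <- xyz[, seq(2, 3 * nat, by = 3), drop = FALSE]
    arr[, , 3] <- xyz[, seq(3, 3 * nat, by = 3), drop = FALSE]
    frames[[i]] <- arr
  }
  trajectory_ensemble(topology, frames, frame_interval_ns)
}

# Minimal CHARMM-style DCD writer (no unit cell, no fixed atoms). Exists so
# toy systems can exercise the binary-trajectory code path end to end; the
# package does not write production trajectories.
write_dcd <- function(frames, path) {
  if (length(dim(frames)) != 3L) stopf("frames must be n_frames x n_atoms x 3")
  nf <- dim(frames)[1]; nat <- dim(frames)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(payload_writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
    payload_writer()
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nf          # number of frames
  icntrl[2] <- 1L          # first step
  icntrl[3] <- 1L          # step interval
  icntrl[4] <- nf
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl, con, size = 4, endian = "little")
  }, 84L)
  title <- sprintf("%-80s", "kinflow toy trajectory")
  rec(function() {
    writeBin(1L, con, size = 4, endian = "little")
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84L)
  rec(function() writeBin(as.integer(nat), con, size = 4, endian = "little"), 4L)
  for (f in seq_len(nf)) {
    for (d in 1:3) {
      rec(function() writeBin(as.numeric(frames[f, , d]), con, size = 4,
                              endian = "little"), 4L * nat)
    }
  }
  invisible(path)
}

# Write a toy structure as a PDB file (via bio3d) so the real-data code path
# can be exercised with generated inputs.
write_structure <- function(struct, path) {
  a <- struct$atoms
  bio3d::write.pdb(file = path,
                   type = ifelse(a$is_ligand, "HETATM", "ATOM"),
                   eleno = a$serial, elety = a$name, resid = a$resname,
                   chain = ifelse(a$chain == "", " ", a$chain),
                   resno = a$resno,
                   xyz = as.vector(t(struct$xyz)),
                   elesy = a$element)
  invisible(path)
}

#' Persist a numeric matrix in the package array container
#'
#' The container is a flat little-endian IEEE-754 double file plus a JSON
#' sidecar (`<path>.json`) holding dimensions, dimnames, units and free-form
#' metadata, so intermediate matrices round-trip bit-exactly and remain
#' self-describing.
#'
#' @param x Numeric matrix or array.
#' @param path Output path for the binary payload.
#' @param units Unit string stored in the sidecar (e.g. "angstrom", "bits").
#' @param meta Named list of additional metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_array_container <- function(x, path, units = "", meta = list()) {
  if (!is.numeric(x)) stopf("x must be numeric")
  dims <- dim(x); if (is.null(dims)) dims <- length(x)
  sidecar <- list(dims = as.integer(dims),
                  dimnames = dimnames(x),
                  units = units,
                  storage = "float64-little-endian",
                  meta = meta)
  con <- file(path, "wb")
  writeBin(as.numeric(x), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a matrix from the package array container
#'
#' @param path Path given to [write_array_container()].
#' @return The stored array with dimnames; sidecar metadata in attributes
#'   `units` and `meta`.
#' @export
read_array_container <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(side)) {
    stopf("array container incomplete: need %s and %s", path, side)
  }
  info <- jsonlite::read_json(side, simplifyVector = TRUE)
  n <- prod(info$dims)
  con <- file(path, "rb")
  x <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  close(con)
  if (length(x) != n) stopf("array container truncated: %s", path)
  if (length(info$dims) > 1) dim(x) <- info$dims
  if (!is.null(info$dimnames)) dimnames(x) <- info$dimnames
  attr(x, "units") <- info$units
  attr(x, "meta") <- info$meta
  x
}
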