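# Synthetic ground-truth generators. These stand in for the original MD
# dataset: a discrete Markov chain with known transition matrix (MSM/TPT
# ground truth), a multi-well overdamped diffusion embedded in toy atomic
# coordinates (tICA/clustering ground truth), a directionally coupled binary
# contact process (transfer-entropy ground truth), and toy receptor-ligand
# complexes that trigger chosen interaction-fingerprint bits.

#' Stationary distribution of a transition matrix
#'
#' @param P Row-stochastic square matrix.
#' @return Probability vector `pi` with `pi %*% P = pi`.
#' @export
stationary_distribution <- function(P) {
  check_prob_matrix(P, tol = 1e-10)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

#' Simulate a discrete-state Markov chain
#'
#' @param P Row-stochastic K x K transition matrix.
#' @param n_frames Number of frames to generate.
#' @param init Initial distribution over states; default is the stationary
#'   distribution of `P`.
#' @param seed Integer seed; the same (P, n_frames, init, seed) always yields
#'   the same trajectory.
#' @return Integer vector of states in 1..K.
#' @export
simulate_markov_chain <- function(P, n_frames, init = NULL, seed = 1L) {
  check_prob_matrix(P)
  if (!is_count(n_frames)) stopf("n_frames must be a positive integer")
  K <- nrow(P)
  if (is.null(init)) init <- stationary_distribution(P)
  if (length(init) != K || any(init < 0) || abs(sum(init) - 1) > 1e-8) {
    stopf("init must be a probability vector of length %d", K)
  }
  cum <- t(apply(P, 1, cumsum))
  cum[, K] <- 1  # guard against rounding in findInterval
  with_rng_seed(seed, {
    s <- integer(n_frames)
    s[1] <- findInterval(runif(1), cumsum(init)) + 1L
    if (s[1] > K) s[1] <- K
    u <- runif(n_frames)
    for (t in seq_len(n_frames - 1L)) {
      s[t + 1L] <- findInterval(u[t + 1L], cum[s[t], ]) + 1L
    }
    s
  })
}

#' Simulate overdamped diffusion in a multi-well potential
#'
#' Euler-Maruyama integration of overdamped Langevin dynamics in a potential
#' built as a sum of negative Gaussian wells,
#' `V(x) = -sum_k depth_k * exp(-|x - c_k|^2 / (2 width_k^2))
#'         + confinement/2 * |x - x_mid|^2`,
#' where `x_mid` is the centroid of the well centers. The harmonic term keeps
#' the walker bounded (Gaussian wells alone are flat at infinity, which would
#' let it escape to free diffusion). The update is
#' `x <- x - (D/kT) * grad V * dt + sqrt(2 D dt) * eta` with standard-normal
#' `eta`; with `kT = 0` the dynamics reduce to deterministic gradient descent
#' with mobility `D`.
#'
#' @param centers Well centers: numeric vector (1D) or K x d matrix.
#' @param depths Well depths (energy units), one per well, all positive.
#' @param widths Well widths (same length units as centers); recycled.
#' @param kT Thermal energy; 0 disables noise.
#' @param D Diffusion coefficient (mobility when `kT = 0`).
#' @param confinement Stiffness of the harmonic confinement (energy per
#'   squared length; default 1).
#' @param dt Integration time step.
#' @param n_frames Number of frames.
#' @param x0 Initial position; default first well center.
#' @param seed Integer seed.
#' @return Numeric `n_frames x d` matrix of positions.
#' @export
simulate_multiwell <- function(centers, depths, widths = 1, kT = 1, D = 1,
                               dt = 1e-3, n_frames = 1000L, x0 = NULL,
                               confinement = 1, seed = 1L) {
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 1)
  K <- nrow(centers); d <- ncol(centers)
  if (K < 2 && kT > 0) stopf("at least 2 wells required")
  if (length(depths) != K) stopf("depths must have one entry per well")
  widths <- rep_len(widths, K)
  if (dt <= 0 || D <= 0) stopf("dt and D must be positive")
  if (!is_count(n_frames)) stopf("n_frames must be a positive integer")
  if (is.null(x0)) x0 <- centers[1, ]
  mid <- colMeans(centers)
  grad <- function(x) {
    g <- confinement * (x - mid)
    for (k in seq_len(K)) {
      dx <- x - centers[k, ]
      g <- g + depths[k] * dx / widths[k]^2 *
        exp(-sum(dx^2) / (2 * widths[k]^2))
    }
    g
  }
  mob <- if (kT > 0) D / kT else D
  amp <- if (kT > 0) sqrt(2 * D * dt) else 0
  span <- max(1, diff(range(centers))) + 10 * max(widths)
  lim <- max(abs(centers)) + 50 * span
  with_rng_seed(seed, {
    x <- matrix(0, n_frames, d)
    cur <- as.numeric(x0)
    x[1, ] <- cur
    noise <- if (amp > 0) matrix(rnorm(n_frames * d, sd = amp), n_frames, d)
             else matrix(0, n_frames, d)
    for (t in seq_len(n_frames - 1L)) {
      cur <- cur - mob * grad(cur) * dt + noise[t, ]
      if (any(!is.finite(cur)) || any(abs(cur) > lim)) {
        stopf("multiwell integration diverged at frame %d; reduce dt", t + 1L)
      }
      x[t + 1L, ] <- cur
    }
    x
  })
}

#' Embed a 1D latent trajectory into toy atomic coordinates
#'
#' Builds a two-pseudo-atom system whose interatomic distance is the affine
#' map `intercept + slope * latent`, so a distance featurizer recovers the
#' latent coordinate exactly. Atom A is fixed at the origin; atom B moves
#' along the x axis. Both atoms are glycine C-alpha atoms of residues 1 and 2.
#'
#' @param latent Numeric vector (or 1-column matrix) of latent values.
#' @param slope,intercept Affine map; `intercept + slope * latent` must stay
#'   positive for every frame.
#' @param frame_interval_ns Frame interval of the resulting ensemble.
#' @return A `traj_ensemble` with one trajectory; the map is stored in the
#'   `embedding` attribute.
#' @export
embed_latent_trajectory <- function(latent, slope = 1, intercept = 10,
                                    frame_interval_ns = 1) {
  latent <- as.numeric(latent)
  d <- intercept + slope * latent
  if (any(d <= 0)) stopf("affine map produces non-positive distances; raise intercept")
  topo <- toy_topology(n_res = 2)
  arr <- array(0, dim = c(length(d), 2L, 3L))
  arr[, 2, 1] <- d
  ens <- trajectory_ensemble(topo, list(arr), frame_interval_ns)
  attr(ens, "embedding") <- list(slope = slope, intercept = intercept)
  ens
}

#' Minimal glycine C-alpha topology
#'
#' Builds an n-residue topology with one C-alpha per residue, used by the
#' synthetic embeddings and handy for descriptor-count checks.
#'
#' @param n_res Number of residues.
#' @return A `mol_structure`.
#' @export
toy_topology <- function(n_res = 2) {
  atoms <- data.frame(
    serial = seq_len(n_res),
    name = "CA",
    element = "C",
    resno = seq_len(n_res),
    resname = "GLY",
    chain = "A",
    is_ligand = FALSE,
    stringsAsFactors = FALSE
  )
  xyz <- cbind(x = seq_len(n_res) * 10, y = 0, z = 0)
  structure(list(atoms = atoms, xyz = xyz, source = "toy"),
            class = "mol_structure")
}

#' Simulate directionally coupled binary contact channels
#'
#' Driver channels are i.i.d. Bernoulli(0.5). Each follower copies its driver
#' delayed by `lag` frames, with each copied bit flipped independently with
#' probability `noise_prob`; its first `lag` frames are Bernoulli(0.5). The
#' result is a planted information-flow direction (driver to follower) for
#' validating transfer-entropy estimates.
#'
#' @param n_channels Total number of channels.
#' @param coupling Integer matrix or data frame with columns `driver`,
#'   `follower` (channel indices). A channel may drive several followers; a
#'   follower has exactly one driver.
#' @param lag Coupling delay in frames (>= 1).
#' @param noise_prob Flip probability in [0, 0.5].
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @return Binary `n_frames x n_channels` matrix.
#' @export
simulate_coupled_contacts <- function(n_channels, coupling, lag = 1L,
                                      noise_prob = 0, n_frames = 1000L,
                                      seed = 1L) {
  coupling <- as.data.frame(coupling)
  if (!all(c("driver", "follower") %in% names(coupling))) {
    stopf("coupling must have columns 'driver' and 'follower'")
  }
  ch <- c(coupling$driver, coupling$follower)
  if (any(ch < 1 | ch > n_channels)) stopf("coupling references missing channels")
  if (anyDuplicated(coupling$follower)) stopf("a follower may have only one driver")
  if (!is_count(lag)) stopf("lag must be >= 1")
  if (noise_prob < 0 || noise_prob > 0.5) stopf("noise_prob must be in [0, 0.5]")
  followers <- coupling$follower
  free <- setdiff(seq_len(n_channels), followers)
  with_rng_seed(seed, {
    x <- matrix(0L, n_frames, n_channels)
    for (j in free) x[, j] <- as.integer(runif(n_frames) < 0.5)
    for (r in seq_len(nrow(coupling))) {
      dr <- coupling$driver[r]; fo <- coupling$follower[r]
      if (dr %in% followers) stopf("chained couplings are not supported")
      x[seq_len(lag), fo] <- as.integer(runif(lag) < 0.5)
      src <- x[seq_len(n_frames - lag), dr]
      flips <- as.integer(runif(n_frames - lag) < noise_prob)
      x[(lag + 1L):n_frames, fo] <- bitwXor(src, flips)
    }
    x
  })
}

# Archetype geometry for the toy-complex builder: for each interaction type,
# the protein residue used and the ligand probe placed against it. Sites are
# spaced 40 A apart so bits cannot leak between archetypes.
TOY_ARCHETYPES <- c(apolar = "LEU", aromatic_f2f = "PHE",
                    aromatic_e2f = "PHE", hbond_donor = "SER",
                    hbond_acceptor = "ASN", electro_pos = "LYS",
                    electro_neg = "ASP")

# Hexagonal ring coordinates (radius 1.39 A) in the plane given by in-plane
# unit vectors u, v, centered at ctr.
ring_coords <- function(ctr, u, v, radius = 1.39) {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  t(vapply(ang, function(a) ctr + radius * (cos(a) * u + sin(a) * v),
           numeric(3)))
}

#' Build a toy receptor-ligand complex
#'
#' Places, for each requested interaction type, one protein residue and one
#' ligand probe group so that the minimum relevant atom-pair (or ring
#' centroid) distance equals the requested placement distance exactly. Sites
#' are spatially isolated, so a complex built from all seven archetypes sets
#' exactly the seven intended fingerprint bits.
#'
#' @param spec Data frame with columns `interaction` (one of
#'   `r paste(names(TOY_ARCHETYPES), collapse = ", ")`) and `distance`
#'   (Angstrom, > 0). An empty data frame yields a ligand-only structure.
#' @return A `mol_structure` with ligand atoms flagged; ligand aromatic rings
#'   are recorded in the `ligand_rings` attribute for the fingerprint stage.
#' @export
build_toy_complex <- function(spec) {
  spec <- as.data.frame(spec)
  if (nrow(spec) > 0) {
    if (!all(c("interaction", "distance") %in% names(spec))) {
      stopf("spec needs columns 'interaction' and 'distance'")
    }
    bad <- setdiff(spec$interaction, names(TOY_ARCHETYPES))
    if (length(bad)) stopf("unknown interaction type(s): %s", paste(bad, collapse = ", "))
    if (any(spec$distance <= 0)) stopf("placement distances must be positive")
  }
  rows <- list()
  lig_rings <- list()
  add <- function(name, element, resno, resname, ligand, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, element = element, resno = resno, resname = resname,
      is_ligand = ligand, x = xyz[1], y = xyz[2], z = xyz[3],
      stringsAsFactors = FALSE)
  }
  # Anchor ligand atom so an empty spec still yields a ligand group.
  add("C0", "C", 900L, "LIG", TRUE, c(0, -30, 0))
  ex <- c(1, 0, 0); ey <- c(0, 1, 0); ez <- c(0, 0, 1)
  for (i in seq_len(nrow(spec))) {
    ia <- spec$interaction[i]; d <- spec$distance[i]
    s <- c(40 * i, 0, 0)
    res <- unname(TOY_ARCHETYPES[[ia]])
    rn <- i
    if (ia == "apolar") {
      add("C1", "C", 900L, "LIG", TRUE, s)
      add("CD1", "C", rn, res, FALSE, s + c(d, 0, 0))
      add("CG",  "C", rn, res, FALSE, s + c(d + 0.8, 1.2, 0))
      add("CD2", "C", rn, res, FALSE, s + c(d + 1.5, 2.0, 0))
      add("CB",  "C", rn, res, FALSE, s + c(d + 1.5, 0, 0) + c(0.8, -1.0, 0))
      add("CA",  "C", rn, res, FALSE, s + c(d + 3.0, 0, 0))
    } else if (ia %in% c("aromatic_f2f", "aromatic_e2f")) {
      lr <- ring_coords(s, ex, ey)          # ligand ring, normal along z
      lnames <- sprintf("C%d%d", i, 1:6)
      for (k in 1:6) add(lnames[k], "C", 900L, "LIG", TRUE, lr[k, ])
      lig_rings[[length(lig_rings) + 1L]] <- lnames
      ctr <- s + c(0, 0, d)
      pr <- if (ia == "aromatic_f2f") ring_coords(ctr, ex, ey)   # parallel
            else ring_coords(ctr, ex, ez)                        # perpendicular
      pnames <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      for (k in 1:6) add(pnames[k], "C", rn, res, FALSE, pr[k, ])
      add("CB", "C", rn, res, FALSE, ctr + c(0, 6, 1))
      add("CA", "C", rn, res, FALSE, ctr + c(0, 7.5, 1))
    } else if (ia == "hbond_donor") {
      add("O1", "O", 900L, "LIG", TRUE, s)      # ligand acceptor
      add("OG", "O", rn, res, FALSE, s + c(d, 0, 0))
      add("HG", "H", rn, res, FALSE, s + c(d - 1.0, 0, 0))
      add("CB", "C", rn, res, FALSE, s + c(d + 1.4, 0, 0))
      add("CA", "C", rn, res, FALSE, s + c(d + 2.9, 0.5, 0))
    } else if (ia == "hbond_acceptor") {
      add("N1", "N", 900L, "LIG", TRUE, s)      # ligand donor (no explicit H)
      add("OD1", "O", rn, res, FALSE, s + c(d, 0, 0))
      add("CG",  "C", rn, res, FALSE, s + c(d + 1.23, 0, 0))
      add("ND2", "N", rn, res, FALSE, s + c(d + 1.9, 1.1, 0))
      add("CB",  "C", rn, res, FALSE, s + c(d + 2.0, -1.0, 0))
      add("CA",  "C", rn, res, FALSE, s + c(d + 3.5, -1.0, 0))
    } else if (ia == "electro_pos") {
      add("O2", "O", 900L, "LIG", TRUE, s)      # ligand anionic oxygen
      add("NZ", "N", rn, res, FALSE, s + c(d, 0, 0))
      add("CE", "C", rn, res, FALSE, s + c(d + 1.5, 0, 0))
      add("CD", "C", rn, res, FALSE, s + c(d + 2.5, 1.0, 0))
      add("CA", "C", rn, res, FALSE, s + c(d + 5.0, 1.0, 0))
    } else if (ia == "electro_neg") {
      add("N1", "N", 900L, "LIG", TRUE, s)      # ligand cationic amine
      add("OD1", "O", rn, res, FALSE, s + c(d, 0, 0))
      add("OD2", "O", rn, res, FALSE, s + c(d + 1.0, 1.0, 0))
      add("CG",  "C", rn, res, FALSE, s + c(d + 0.8, -0.9, 0))
      add("CB",  "C", rn, res, FALSE, s + c(d + 2.2, -0.9, 0))
      add("CA",  "C", rn, res, FALSE, s + c(d + 3.7, -0.9, 0))
    }
  }
  df <- do.call(rbind, rows)
  atoms <- data.frame(serial = seq_len(nrow(df)), name = df$name,
                      element = df$element, resno = df$resno,
                      resname = df$resname, chain = "A",
                      is_ligand = df$is_ligand, stringsAsFactors = FALSE)
  xyz <- cbind(x = df$x, y = df$y, z = df$z)
  out <- structure(list(atoms = atoms, xyz = xyz, source = "toy_complex"),
                   class = "mol_structure")
  attr(out, "ligand_rings") <- lig_rings
  out
}
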