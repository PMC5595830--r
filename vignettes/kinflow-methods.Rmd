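---
title: "Methods: kinetic models and information flow for receptor activation trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinetic models and information flow for receptor activation trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model

`kinflow` analyses ensembles of molecular-dynamics trajectories of a
G protein-coupled receptor (GPCR) transitioning between inactive and
activated conformations. The pipeline is the field's standard Markov-state
modelling stack, built here as one coherent, tested package:

1. **Featurization.** Frames are described by three descriptor families:
   all C-alpha pair distances over a thinned residue selection (one residue
   in three between the first and last analysed residues keeps the
   quadratic family tractable: 97 residues give 4,656 pairs), binary
   sidechain-sidechain contacts (minimum sidechain heavy-atom distance
   below 7 Å in at least one reference crystal structure), and binary
   residue-ligand contacts (7 Å heavy-atom cutoff, one descriptor per
   residue of the analysed span).
2. **tICA.** Time-lagged independent component analysis solves the
   generalized eigenproblem `C^tl(τ) U = C U Λ` on the instantaneous and
   lagged covariances of the mean-centered features. Eigenvectors with the
   largest eigenvalues are the slowest linear coordinates; the first 10 are
   kept by default.
3. **MSM.** Projected frames are discretized with k-means (k-means++
   seeding), sliding-window transition counts are collected at a lag, and a
   transition matrix is estimated by maximum likelihood under detailed
   balance. Implied timescales `t_i = −τ/ln|λ_i|` must be flat in the lag,
   and a Chapman–Kolmogorov test compares `T(τ)^m` against re-estimation at
   `mτ`.
4. **PCCA+.** Microstates are lumped into metastable macrostates from the
   simplex structure of the dominant right eigenvectors; macrostate
   probabilities are sums of microstate stationary probabilities.
   Macrostates are classified into activation regions from two order
   parameters: the TM3–TM6 C-alpha distance and the NPxxY-segment RMSD from
   the inactive reference.
5. **TPT.** Committors, reactive fluxes, a bottleneck-removal pathway
   decomposition, and mean first-passage times characterize the
   activation/deactivation transitions between chosen macrostates.
6. **Transfer entropy + HITS.** Directed information flow between residues
   is the plug-in transfer entropy on per-residue binary contact vectors,
   bias-corrected by subtracting the estimate computed with time-shuffled
   source symbols. HITS on the resulting weighted directed graph yields
   authority (receiver) and hub (transmitter) scores; nodes strong in both
   are connectors.
7. **Fingerprints.** Ligand binding modes are encoded per residue as 7
   bits: apolar, aromatic face-to-face, aromatic edge-to-face, H-bond with
   the protein as donor, H-bond with the protein as acceptor, and
   electrostatic contacts of positively or negatively charged sidechains.
8. **Errors.** A trajectory bootstrap (500 samples, each 95% of the
   trajectories drawn without replacement, all frames kept) reports first
   and third quartiles of any estimate.

The assumptions are those of every MSM analysis: trajectories sample local
equilibrium within microstates at the analysis lag; dynamics at that lag
are approximately Markovian in the discretized slow subspace (checked, not
assumed, via implied-timescale convergence and the CK test); and the
reversible estimator presumes detailed balance of the underlying dynamics.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| sidechain/ligand contact cutoff | 7 | Å | standard heavy-atom contact definition for coarse contact maps |
| tICA lag | = MSM lag | frames | no separate slow-scale parameter; one time resolution |
| tICA components | 10 | – | marginals become near-normal beyond the first ~10 components |
| ridge on `diag(C)` | `1e-8 · tr(C)/d` | feature units² | binary contact columns make `C` rank-deficient |
| microstates k | 1000 (full scale) | – | fine discretization; ±10% changes little |
| MSM lag | 10 ns in frame units | frames | implied timescales converge at ~10 ns for these systems |
| macrostates | 14 (full scale) | – | keeps intra-state order-parameter spread within a few Å |
| inactive region | distance ≤ 10 Å and RMSD ≤ 2.5 Å | Å | explicit inactive-region rule |
| outer distance bound `dist_active` | 13 | Å | landscape boundary between intermediate-II and fully outward TM6; configurable because only the inactive rule is numerically fixed |
| TE subsampling | 30%, 3 repeats | – | cost control with averaging |
| fingerprint cutoffs | 4.5 (apolar), 4 (aromatic/electrostatic), 3.5 (H-bond) | Å | standard SIFt apolar/aromatic/electrostatic cutoffs; H-bond distance is the conventional geometric criterion |
| bootstrap | 500 samples, 95% | – | standard error protocol for trajectory ensembles |

Comparison conventions are fixed so bit-level tests are possible: contact
and apolar/electrostatic thresholds use strict `<`; the aromatic centroid
and H-bond distances use `≤`. Region boundaries are inclusive on the
inactive side.

# What the synthetic generators emulate

The original trajectory datasets of this kind (hundreds of microseconds of
ligand-bound receptor dynamics) are not redistributable, so every stage is
validated against generators with known ground truth:

* `simulate_markov_chain` — microstate dynamics with a known transition
  matrix; ground truth for stationary distributions, implied timescales,
  CK, TPT and the bootstrap.
* `simulate_multiwell` — overdamped Langevin dynamics in a sum of Gaussian
  wells plus a weak harmonic confinement (`confinement`, default 1 energy
  per squared length). The confinement is needed because Gaussian wells are
  flat at infinity; without it the walker eventually escapes to free
  diffusion. `embed_latent_trajectory` maps the latent coordinate affinely
  onto a two-pseudo-atom distance so the featurizer and tICA can recover it
  exactly.
* `simulate_coupled_contacts` — binary channels where followers copy their
  driver with a delay and flip noise; the lag-1 noiseless copy has exactly
  1 bit of transfer entropy in the forward direction and 0 backward.
* `build_toy_complex` — residue/ligand probe pairs placed at exact
  distances on isolated sites (40 Å apart), so each fingerprint bit can be
  switched on and off at its cutoff independently.

What passing these tests does **not** show: real receptor data are
high-dimensional, non-Markovian at short lags, unevenly sampled, and full
of correlated descriptors; the synthetic systems probe correctness of the
estimators, not robustness to all of that. The end-to-end pipeline default
is a double-well system scaled so each trajectory crosses the barrier a
few times (20 trajectories × 3,000 frames, depths 4 kT, widths 0.4, step
0.01); with fewer crossings the stationary split would be irrecoverable by
any estimator.

# Numerical choices

* **tICA.** `C^tl` is symmetrized before the eigenproblem, guaranteeing a
  real spectrum (the standard reversible estimator); the generalized
  problem is solved via Cholesky whitening of the ridge-regularized `C`.
  Each eigenvector's largest-magnitude loading is made positive, making
  signs deterministic.
* **Reversible MLE.** Self-consistent fixed-point iteration on symmetric
  flows, converged when the largest relative change is below 1e-10 (cap
  10⁶ iterations), after trimming to the largest strongly connected count
  set. Two-state chains reproduce the closed form exactly.
* **PCCA+.** Inner simplex algorithm on the top right eigenvectors; the
  first vertex is the row farthest from the origin, subsequent vertices
  maximize the residual after projecting out previous directions. Crisp
  states by maximal membership. Macrostates are renumbered by decreasing
  equilibrium probability so labels are reproducible across runs; a
  degenerate eigenvalue pair at the spectral cut is an error (the lumping
  would be arbitrary), as is an empty macrostate.
* **Pathway decomposition.** Iterative bottleneck removal: repeatedly take
  the widest (maximum-bottleneck) source→sink path, assign it its
  bottleneck flux, subtract, and stop when the residual is exhausted;
  residual flux that cannot reach the sink raises an error. This is a
  deterministic, documented choice among the several decompositions in
  use.
* **Transfer entropy.** The defining sum is evaluated through the identity
  `TE = H(x⁺,x) − H(x) − H(x⁺,x,y) + H(x,y)` (log base 2 → bits); tests
  assert exact equality with direct summation over the empirical joint
  distribution. Each node's per-frame contact vector is one discrete
  symbol — contacts are binary, so no binning is involved. The shuffle
  baseline permutes the source's time indices within each trajectory (one
  permutation by default, configurable). Negative corrected values are kept
  in the matrix but clipped to zero for graph construction, since HITS
  needs non-negative weights.
* **Degenerate inputs.** Glycine, which has no sidechain heavy atoms, is
  represented by its C-alpha in contact and fingerprint calculations.
  Constant descriptor columns get correlation 0 with a flag. Near-unit
  eigenvalues are reported as infinite timescales with a flag rather than
  propagated as overflow.
* **State labels** are 1-based integers (R convention) everywhere; frames
  within a trajectory are indexed from 1.

# Open design points, resolved

* The tICA lag is not separately specified at full scale; it defaults to
  the MSM lag so the analysis has one time-resolution parameter.
* Descriptor–component correlation is plain Pearson correlation on the raw
  descriptor traces, ranked by absolute value (top 75 by default).
* The four-region landscape grid is only numerically fixed on the inactive
  side; the outer TM3–TM6 bound (13 Å) is configurable, and averages in
  the unpopulated cell (intermediate distance with inactive-like NPxxY) are
  reported as unclassified rather than forced into a region.
* Macrostate-to-macrostate MFPTs use the full target macrostate's
  microstate set as the absorbing set and average over the source set with
  the stationary distribution restricted to it.
* H-bond geometry (never fully specified in the fingerprint literature
  this follows): donor–acceptor heavy-atom distance ≤ 3.5 Å, plus a
  D–H⋯A angle ≥ 120° when explicit hydrogens exist.
* Atom typing for fingerprints is disjoint: aromatic-ring carbons count as
  aromatic, not apolar, so a stacking interaction does not automatically
  set the apolar bit. Ligand atoms default to element-based typing
  (non-ring C/S apolar, N donor/cation candidate, O acceptor/anion
  candidate) and can be overridden per atom.

# Error protocol and its quartile interval

`bootstrap_trajectories` implements this protocol literally:
resample 95% of the trajectories without replacement, keep all frames,
re-estimate, and report the first and third quartiles of 500 estimates.
Note what such an interval is: the spread of delete-5% subsample estimates
is roughly `sqrt(0.05/0.95) ≈ 0.23` times the sampling standard error of
the full estimate, so the Q1–Q3 band is an *internal stability* indicator,
not a confidence interval — it cannot be expected to contain the true
parameter value in most repeated experiments. The acceptance suite runs
this coverage experiment and reports the measured coverage.

# Known limitations

* XTC trajectories are not readable (no installed reader); DCD and
  multi-model PDB are supported, and a minimal DCD writer exists for
  exercising the binary path with generated data.
* The committor/MFPT linear solves are dense; they are comfortable at the
  ~1000-microstate scale the method targets but not beyond.
* Transfer entropy is pairwise only; no conditional or multivariate
  variants.
* PCCA+ returns crisp states by maximal membership; fuzzy memberships are
  exposed but downstream statistics use the crisp assignment.
* The four-region classification needs two order parameters; synthetic
  1-D systems fill the second with a constant, exercising the rule but not
  the full grid.

# Problem sizes used in the test and acceptance runs

Synthetic checks run at sizes chosen to make their statistical tolerances
meaningful: 10⁵–10⁶ frames for stationary/timescale recovery and
transfer-entropy calibration (binomial/spectral error well below the
asserted tolerances), 10³ frames for exact-identity checks, and a
10-trajectory double-well system for the end-to-end pipeline. The
bootstrap coverage experiment uses 50 independent experiments of 30
trajectories × 1,000 frames with the full 500-sample protocol.
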