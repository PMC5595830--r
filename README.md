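# kinflow

Markov state models, transition path theory and directed information flow
for molecular-dynamics trajectory ensembles of receptor activation.

## The problem

Class-A G protein-coupled receptors (GPCRs) such as the µ-opioid receptor
activate through a cascade of conformational changes — the outward swing of
transmembrane helix 6 relative to helix 3, the backbone distortion of the
conserved NPxxY motif — that unfold over microseconds to milliseconds.
High-throughput MD produces thousands of short trajectories of such
systems; turning them into thermodynamics (state populations), kinetics
(relaxation timescales, transition pathways, mean first-passage times) and
mechanism (which residues drive which) requires a statistical pipeline:

1. **Featurize** frames as Cα pair distances, sidechain contact maps and
   residue–ligand contacts.
2. **tICA** — solve the generalized eigenproblem `C^tl(τ) U = C U Λ` on
   instantaneous and time-lagged feature covariances; the top eigenvectors
   are the slowest linear coordinates.
3. **MSM** — k-means microstates in tICA space, then a reversible
   maximum-likelihood transition matrix `T(τ′)` from sliding-window counts,
   validated by implied timescales `t_i = −τ′/ln|λ_i(τ′)|` and a
   Chapman–Kolmogorov test.
4. **PCCA+** — lump microstates into metastable macrostates, classify them
   into inactive / intermediate I / intermediate II / active regions of the
   activation landscape.
5. **TPT** — committors, reactive flux `f_ij = π_i(1−q_i)T_ij q_j`,
   flux-ranked pathway decomposition, MFPTs.
6. **Transfer entropy + HITS** — shuffle-corrected plug-in transfer entropy
   on binary contact dynamics defines a directed residue graph; HITS
   authority/hub scores rank receivers, transmitters and connectors of
   information.
7. **Interaction fingerprints** — a 7-bit per-residue encoding of the
   ligand binding mode (apolar, aromatic face/edge, H-bond donor/acceptor,
   electrostatic ±).
8. **Bootstrap** — quartile error bars from 500 resamples of 95% of the
   trajectories.

`kinflow` implements this pipeline as plain R with classed S3 results
(`print`/`summary`/`predict` methods), plus a synthetic-data module that
generates every input with known ground truth — Markov chains with known
`T`, multi-well diffusions embedded in toy coordinates, coupled binary
contact processes with a planted information-flow direction, and toy
complexes that trigger chosen fingerprint bits — so the whole stack is
testable without access to the original MD datasets. See the methods
vignette (`vignettes/kinflow-methods.Rmd`) for models, assumptions and
design decisions.

## Worked example

A double-well diffusion embedded in a pseudo-atomic distance, analysed end
to end (every number shown is the script's actual output):

```r
library(kinflow)
latent <- lapply(1:10, function(i)
  simulate_multiwell(c(-1, 1), depths = c(4, 4), widths = 0.4,
                     kT = 1, dt = 0.01, n_frames = 3000,
                     x0 = c(-1, 1)[1 + i %% 2], seed = i))
topo <- toy_topology(2)
ens <- trajectory_ensemble(topo,
  lapply(latent, function(l)
    embed_latent_trajectory(l[, 1], slope = 3, intercept = 11)$frames[[1]]),
  frame_interval_ns = 1)
feats  <- compute_features(ens, build_descriptor_set(topo, 1:2))
tica   <- estimate_tica(feats, lag = 10, n_components = 1)
assign <- cluster_microstates(predict(tica, feats), k = 20, seed = 1)
msm    <- estimate_msm(assign, lag = 10, frame_interval_ns = 1)
msm
#> markov_model: 20 states, lag 10 frames (10 ns)
#> leading eigenvalues: 1.0000 0.9773 0.6951 0.3188 0.2311

macro <- pcca_lump(msm, 2)
macro
#> macrostate_model: 2 macrostates over 20 microstates
#> equilibrium probabilities: 0.559 0.441

mfpt(msm, macro$active[macro$assignment == 1],
          macro$active[macro$assignment == 2])
#> mfpt: 90.966 steps (909.66 frames, 909.66 ns)

implied_timescales(assign, lags = c(5L, 10L, 20L), n_timescales = 1,
                   frame_interval_ns = 1)[, c("lag_frames", "timescale_ns")]
#>   lag_frames timescale_ns
#> 1          5     425.0903
#> 2         10     435.4006
#> 3         20     449.2991
```

Reading: the two wells are recovered as two macrostates with populations
0.56/0.44 (the planted split is 0.5/0.5; ten trajectories of 3,000 frames
leave that much sampling error), the slowest implied timescale is stable
(~425–450 ns) across a four-fold range of lags — the Markovian-lag
diagnostic — and the well-to-well MFPT is ~0.9 µs in the toy units.

`run_pipeline(pipeline_config(...))` runs the same stack plus transfer
entropy/HITS, fingerprints and the bootstrap in one call, persists every
stage, and `generate_report()` renders CSV tables and figures.

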