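---
title: "Dissecting correlated domain motion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting correlated domain motion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrnet)
```

# Scope

corrnet analyzes molecular dynamics trajectories of bilobal proteins
(the motivating systems are SET-domain lysine methyltransferases, whose
N-lobe and C-terminal lobe flank the substrate cleft) for *correlated
domain motion*: which residues move together, which move in opposition,
and along which residue-residue contact routes the two lobes
communicate. The pipeline chains four analyses that are standard in the
field:

1. **Superposition and fluctuation statistics.** Every frame is fitted
   onto a reference by the Kabsch least-squares rotation; RMSD per
   frame, RMSF per residue, and the crystallographic comparison
   $B = \frac{8\pi^2}{3}\,\mathrm{RMSF}^2$ (isotropic harmonic model).
2. **Dynamic cross-correlation map (DCCM).**
   $C_{ij} = \langle \Delta r_i \cdot \Delta r_j\rangle /
   \sqrt{\langle|\Delta r_i|^2\rangle\langle|\Delta r_j|^2\rangle}$
   over C$\alpha$ displacement vectors; $-1$ is fully anti-correlated
   motion, the signature of lobes closing on a cleft.
3. **Essential dynamics.** Eigen-decomposition of the $3N \times 3N$
   Cartesian coordinate covariance of C$\alpha$ atoms; leading
   eigenvectors are the concerted motions (e.g. inter-lobe twist,
   clamshell opening), and conformers are clustered in the PC1-PC2
   plane by k-means and complete-link hierarchical clustering with the
   BSS/TSS ratio as quality score.
4. **Dynamical network analysis.** Residues (one node per amino acid,
   anchored at C$\alpha$; ligands may contribute several named-atom
   nodes, e.g. the cofactor product SAH at CA, C4', N9) are joined by
   an edge when they stay within a 4.5 Å contact cutoff for at least
   75% of the trajectory. Edge distances $w_{ij} = -\ln|C_{ij}|$
   convert correlation into an information-transfer length, so
   shortest paths are the most probable communication routes.
   Girvan-Newman removal of maximum edge-betweenness edges yields
   communities (scored by Newman modularity $Q$), critical nodes mark
   community interfaces, and optimal/suboptimal path enumeration maps
   allosteric routes between chosen endpoints.

# The synthetic world

No reference trajectory is distributed with the methodology this
package implements, so correctness rests on generators with planted,
analytically known structure.

**Gaussian ensembles** (`generate_gaussian_ensemble`) draw frames
$r_f = \mu + \Delta r_f$, $\Delta r_f \sim N(0, \Sigma)$ for a chosen
$3N \times 3N$ covariance. `planted_block_covariance` builds
$\Sigma = v\, K \otimes I_3$ from a node-level correlation matrix $K$
(unit diagonal, `intra` within blocks, `inter` across). Because the
expansion is isotropic, the population DCCM of the ensemble equals $K$
entry-for-entry — the *analytic oracle* for correlation recovery. The
default stated world is 40 nodes in two blocks, intra $+0.7$, inter
$-0.6$, per-coordinate variance $0.25\,\text{Å}^2$ (RMSF
$\approx 0.87$ Å, a realistic mobile-loop amplitude), 2000 frames —
the frame count of a 2 ns run sampled every 1 ps.

**Two-lobe mechanism** (`generate_two_lobe_trajectory`). Two rigid
cubic-lattice lobes (3.8 Å spacing, the C$\alpha$ virtual-bond length)
face each other across a 15 Å cleft and are joined by a single file of
bridge nodes — the synthetic analog of a lobe-bridging $\beta$
hairpin. Per frame the lobes counter-rotate about a hinge axis by a
clamshell angle $\sim N(0, 5^\circ{}^2)$ and about the inter-lobe axis
by a twist angle $\sim N(0, 3^\circ{}^2)$; bridge nodes interpolate
the two rotations linearly, and isotropic noise of 0.3 Å is added.
Geometry places the lobe centroids at polar angle $\pm 25^\circ$ from
the hinge so that counter-rotation opens and closes the cleft; the
bridge is laid between the two facing extreme nodes, guaranteeing by
construction a unique inter-lobe contact path with spacing
`gap/(bridge_nodes + 1)`. With the default 4 bridge nodes that spacing
is 3 Å < 4.5 Å; *if you shrink `bridge_nodes`, shrink `gap`
accordingly or the contact chain breaks* (the package treats this as
part of the stated geometry, not as an error).

What a green test establishes: recovery of planted correlation signs
and magnitudes, of planted spectra, cluster labels, communities and
bridge-constrained paths. What it does not: force-field realism,
solvent effects, time-correlation (frames are i.i.d. draws),
convergence behavior of real MD, or side-chain contact geometry
(lobes are C$\alpha$-only; the heavy-atom contact mode is exercised on
hand-built multi-atom fixtures instead).

**Planted graphs** (`generate_planted_graph`) build clique communities
with high-|C| edges joined by sparse low-|C| bridges, returning the
planted labels for adjusted-Rand scoring.

# Numerical and design choices

- **Alignment vs planted statistics.** Kabsch fitting removes each
  frame's best-fit rigid component. For a fixed-frame Gaussian
  ensemble this *distorts* the planted correlations (the two-block
  world's inter-block mean moves from $-0.6$ to about $-0.69$, because
  the fit strips the shared translational component). Planted-value
  recovery is therefore evaluated on the unaligned ensemble, where the
  sample DCCM is an unbiased estimate of the analytic $K$; the aligned
  path is checked qualitatively (sign and magnitude ordering). Real
  trajectories, which diffuse, must always be aligned first.
- **B-factor conversion** uses the isotropic harmonic relation; no
  rescaling is applied when comparing simulation RMSF with
  B-derived RMSF — both are reported on common axes.
- **"Backbone" RMSD** falls back to C$\alpha$-only whenever N, C, O
  atoms are absent, which is always the case for the synthetic worlds.
- **PCA** diagonalizes the plain (unweighted) Cartesian covariance —
  C$\alpha$-only input makes mass weighting immaterial — with
  eigenvalues descending, ties left in first-occurrence order, and
  eigenvector signs fixed by making the largest loading positive.
- **k-means** is Lloyd iteration, 25 seeded restarts, centers
  initialized from distinct sampled frames, empty clusters re-seeded
  with the worst-fit point; BSS/TSS $= 1 - \mathrm{WSS}/\mathrm{TSS}$.
  `elbow_scan` additionally seeds each $k$ with the previous solution
  plus one split-off center, which makes the BSS/TSS curve provably
  non-decreasing.
- **The elbow rule.** The spec of this package originally proposed the
  absolute second difference of the BSS/TSS curve as the elbow.
  Implementation showed that rule is dominated by the first large
  split (for four well-separated blobs it suggests $k = 2$), so the
  shipped rule is the *relative* gain drop: suggest the $k$
  maximizing $g_k / g_{k+1}$, $g_k$ the BSS/TSS gain at $k$, over
  $k$ with non-negligible gain ($\ge$ 1% of total). The suggestion is
  advisory (the cluster count remains a user parameter) and is
  flagged low-confidence when the drop is < 3-fold or > 10% of the
  achievable gain remains beyond the suggested $k$ — both thresholds
  fixed once, before testing against held-out shapes.
- **Network conventions.** $w = -\ln|C|$ (the information-transfer
  convention of the VMD/NetworkView protocol family); the same Pearson
  DCCM feeds Fig-style maps and edge weights; contact persistence
  uses strict `< cutoff` per frame and inclusive `>= 75%` on the
  fraction; sequence-neighbor exclusion defaults to 1 because bonded
  neighbors are trivially in contact and would short-circuit paths.
  The two-lobe *fixture* runs with exclusion 0: its bridge is a chain
  of sequence-consecutive nodes, so exclusion 1 would sever the only
  inter-lobe path — a property of the coarse synthetic chain, not of
  real hairpins, whose strands pair non-consecutive residues.
  Non-ligand HETATM residues (ions, waters) are excluded from node
  maps unless a ligand rule names them.
- **Determinism.** Every stochastic routine is a pure function of
  (spec, seed) and restores the caller's RNG state. Graph ties are
  broken by lowest endpoint pair; equal-modularity partitions resolve
  to the earliest in the removal sequence; suboptimal paths sort by
  (length, lexicographic sequence). Two pipeline runs with the same
  config and seed produce byte-identical summaries.
- **Suboptimal tolerance.** "Slightly longer than optimal" is not
  sharp; the default is $\delta = 0.2\,L_{\mathrm{opt}}$, always
  reported alongside the path set, with a hard cap and truncation
  flag for pathological graphs.
- **Critical nodes** are the endpoints of the maximum edge-betweenness
  edge between each connected community pair. At a bridge-lobe
  interface one endpoint necessarily lies inside a lobe; the
  meaningful planted-world property, and the one the acceptance test
  asserts, is that every inter-lobe critical edge touches the bridge
  and all inter-lobe paths cross it.

# Degenerate inputs

Superposition requires $\ge 3$ non-collinear atoms; zero-variance
nodes get zeroed DCCM rows (diagonal kept at 1) with a warning;
zero-correlation edges are dropped from networks with a warning
(infinite distance); empty networks, unknown node labels, disconnected
path endpoints, inconsistent multi-model topologies and out-of-range
thresholds raise immediate, named errors. Distance-deviation maps
accumulate deviations from the first frame's distances to avoid
catastrophic cancellation on large, nearly constant distances.

# Known limitations

- Multi-model PDB is the only trajectory format; binary formats (DCD,
  XTC) would need an external conversion step.
- Girvan-Newman recomputes edge betweenness after every removal
  ($O(m^2 n)$ overall), appropriate for residue networks of a few
  hundred nodes, not for much larger graphs.
- Frames are treated as independent draws; no statistical-inefficiency
  or autocorrelation correction is applied to any error estimate.
- Heavy-atom contact mode loops over residue pairs in R and is meant
  for modest systems.

# A minimal run

```{r example, eval = FALSE}
spec <- two_lobe_spec(seed = 42)
traj <- generate_two_lobe_trajectory(spec)
truth <- attr(traj, "truth")
cfg <- pipeline_config(
  trajectory = traj, exclude_neighbors = 0L, cluster_k = 2L,
  path_source = truth$lobe_b[1], path_target = truth$lobe_a[1],
  group_a = truth$lobe_a, group_b = truth$lobe_b,
  seed = 7L, out_dir = "two-lobe-run")
report <- run_pipeline(cfg)
report$summary$dccm$block$dccm_inter_mean   # negative: lobes anti-correlated
report$summary$network$n_communities        # >= 2, split along the lobes
report$paths$optimal                        # passes through the bridge nodes
```
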