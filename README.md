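# corrnet

Correlated-motion and dynamical network analysis of molecular dynamics
trajectories, in R.

Bilobal enzymes — the motivating case is the SET-domain lysine
methyltransferase family, where an N-lobe and a C-terminal lobe flank
the substrate cleft — regulate substrate access through concerted
opening/closing and twisting of their lobes. Given a trajectory (a
multi-model PDB, one structure per `MODEL` block) corrnet answers, in
one reproducible pipeline:

- **How much does each residue move?** Kabsch superposition, per-frame
  RMSD, per-residue RMSF, and the crystallographic comparison via
  `B = (8π²/3)·RMSF²`.
- **Which residues move together, which in opposition?** The dynamic
  cross-correlation map (DCCM)
  `C_ij = ⟨Δr_i·Δr_j⟩ / √(⟨|Δr_i|²⟩⟨|Δr_j|²⟩)`, plus inter-residue
  distance deviation maps and pair distance series.
- **What are the concerted motions?** PCA of the 3N×3N Cα coordinate
  covariance (essential dynamics): scree fractions `λ_k/Σλ`, frame
  projections, interpolated structures along a mode, and conformer
  clustering in the PC1–PC2 plane (seeded Lloyd k-means and
  complete-link hierarchical clustering, scored by BSS/TSS, with an
  elbow scan).
- **Along which routes do the lobes communicate?** A dynamical network
  with one node per residue (ligands may contribute several, e.g. SAH
  at atoms CA, C4', N9), edges where residues stay within 4.5 Å for at
  least 75% of frames, and edge distances `w = −ln|C|`. On it:
  Girvan–Newman communities with modularity Q, betweenness, critical
  nodes at community interfaces, and optimal/suboptimal path
  enumeration between chosen endpoints.

Because reference MD trajectories for this methodology are typically
not deposited, corrnet ships synthetic generators with planted,
analytically known structure — Gaussian ensembles with a planted
displacement covariance, a two-lobe clamshell/twist mechanism with a
narrow bridge (the analog of a lobe-bridging β hairpin), and
planted-community graphs — and its whole test suite runs against these
oracles.

## Worked example

```r
library(corrnet)

spec  <- two_lobe_spec(seed = 42)            # 36 nodes, 2000 frames, 1 ps
traj  <- generate_two_lobe_trajectory(spec)
truth <- attr(traj, "truth")                 # planted lobe/bridge labels

cfg <- pipeline_config(
  trajectory  = traj,
  exclude_neighbors = 0L,                    # synthetic bridge is a chain
  cluster_k   = 2L,
  path_source = truth$lobe_b[1], path_target = truth$lobe_a[1],
  group_a     = truth$lobe_a,    group_b     = truth$lobe_b,
  seed = 7L, out_dir = "two-lobe-run")
report <- run_pipeline(cfg)
```

Output of this exact run:

```
> report$summary$dccm$block$dccm_inter_mean
[1] -0.772
> report$summary$network$n_communities
[1] 4
> report$summary$network$modularity
[1] 0.523
> paste(report$paths$optimal, collapse = " -> ")
[1] "ALA25 -> ALA30 -> ALA24 -> ALA23 -> ALA22 -> ALA21 -> ALA3 -> ALA1"
> length(report$paths$paths)
[1] 9
```

Read: the two lobes are strongly anti-correlated (mean inter-lobe DCCM
−0.77, the planted clamshell signature); the network splits into 4
communities, none mixing the lobes; the optimal communication path
from the C-lobe analog (ALA25) to the N-lobe analog (ALA1) runs
through all four planted bridge nodes (ALA21–ALA24), and all 9
suboptimal paths cross the bridge — the synthetic counterpart of a
hairpin-mediated inter-lobe allosteric route. `two-lobe-run/` holds
the TSV/GraphML/JSON artifacts (`rmsd.tsv`, `dccm.tsv`, `scree.tsv`,
`clusters.tsv`, `communities.tsv`, `edges.tsv`, `network.graphml`,
`paths.tsv`, `summary.json`), each stamped with the seed and a config
hash; identical config + seed reproduces `summary.json` byte for byte.

A command-line mirror of each stage is available:

```sh
Rscript -e 'corrnet::corrnet_cli()' simulate --spec two-lobe-default --out sim --seed 3
Rscript -e 'corrnet::corrnet_cli()' run-all --traj sim/two-lobe-default.pdb --out run1 --seed 3
```

(subcommands: `simulate`, `align`, `rmsf`, `dccm`, `pca`, `cluster`,
`network`, `paths`, `run-all`).

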