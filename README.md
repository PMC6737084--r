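# ercoupler

Trajectory diagnostics for mutant estrogen-receptor-α (ERα) pharmacology.

Point mutations in the ERα ligand-binding domain (Y537S, Y537N, D538G) drive
endocrine-therapy resistance in metastatic breast cancer by locking helix 12
(H12) in an agonist-like pose. Molecular-dynamics studies of these mutants
diagnose activation state and antiestrogen action from a handful of recurring
computations: dynamic cross-correlation maps and inter-helix coupling scores,
conformational clustering, hydrogen-bond persistence of the ligand anchors
(L346, E419, K529), metadynamics dissociation barriers, and virtual-screening
funnels over several receptor conformations. `ercoupler` implements that
analysis surface as a tested, reusable R package, validated end-to-end on
synthetic trajectories and toy energy landscapes with known ground truth.

## What it computes

**Correlation analysis.** For atoms *i*, *j* (one representative atom per
residue, Cα by default) the scalar covariance of positional fluctuations is

    C_ij = ⟨ (r_i − ⟨r_i⟩) · (r_j − ⟨r_j⟩) ⟩

over an RMS-fitted trajectory, normalized to Pearson coefficients
`CC_ij = C_ij / sqrt(C_ii C_jj)` ∈ [−1, 1] (the DCCM). Inter-segment
correlation scores (CS) between helices I and J discard the noise band
−0.6 < CC < +0.6 and divide the surviving sum by the product of the numbers
of contributing residues (a correlation density). A positive H12↔H3–H5 score
is the structural signature of constitutive mutant activation; effective
antiestrogens remove it. Per-residue profiles against a focus helix (e.g.
H12) resolve the coupling residue by residue.

**Structure analysis.** Pairwise-fitted RMSD, greedy RMSD-cutoff (Daura)
conformational clustering with a deterministic lowest-index tie-break, and
donor–H–acceptor hydrogen-bond occupancy (defaults: D–A ≤ 3.5 Å, angle at H
≥ 120°).

**Metadynamics.** Standard (fixed-height) metadynamics over two collective
variables — a contact coordination number with the rational switch
`s(r) = (1−(r/r0)^6)/(1−(r/r0)^12)` and a centre-of-mass separation in nm —
with Gaussian hill deposition (default 0.6 kJ/mol), a one-sided harmonic
wall, FES reconstruction as the negated accumulated bias, lowest-saddle
(minimax) barrier extraction on the FES grid, and replica aggregation
(mean ± sample sd, in kcal/mol). A compiled BAOAB Langevin engine runs the
method on toy potentials whose barriers are known in closed form.

**Screening.** Lipinski rule-of-five plus rotatable-bond (≤ 10) filtering
with per-rule rejection tallies; two consensus selections over per-target
docking scores (structure-based: best score ≤ −8.5 kcal/mol on ≥ 1 of the
five mutant-receptor conformations; ligand-based: poses on ≥ 2 conformations
with ≥ 1 score ≤ −7.5 kcal/mol); ligand efficiency LE = ΔG_b / heavy atoms.

**Synthetic data.** Seeded generators with machine-readable ground truth for
every input class: block-correlated Cα trajectories (exact target CC),
H-bond systems with designed occupancy, compound tables with designed
per-rule pass rates, and toy potentials (1-D double well, two-channel 2-D
surface, host–guest particle system).

## Worked example

```r
library(ercoupler)

# helix coupling on a synthetic trajectory with a designed H3-H12 correlation
segments <- make_segment_map(c("H3", "H12"), start = c(342, 536), end = c(363, 544))
sim <- generate_correlated_trajectory(
  segments, within_block_rho = 0.9,
  cross_block_rho = list("H3:H12" = 0.8),
  n_frames = 5000, seed = 42)
cc <- cross_correlation_matrix(covariance_matrix(sim$trajectory))
segment_correlation_score(cc, sim$topology, segments, threshold = 0.6)
#> # A tibble: 1 × 6
#>   segment_i segment_j score n_contributing_pairs n_residues_i n_residues_j
#> 1 H3        H12       0.800                  198           22            9
```

The designed cross-block correlation (0.8) is recovered as the H3–H12 score:
198 residue pairs survive the ±0.6 noise filter, and the thresholded sum
divided by 22 × 9 contributing residues gives back 0.800.

```r
# dissociation barrier of a 5 kT double well by standard metadynamics
kT <- KB_KJ_MOL_K * 310
pot <- make_toy_potential("double_well_1d", h = 5 * kT)   # barrier 12.89 kJ/mol
grid <- list(list(min = -2.2, max = 2.2, n = 881))
barriers <- sapply(1:3, function(s) {
  cfg <- mtd_config(hill_height = 0.6, hill_widths = 0.1, pace = 500,
                    temperature = 310, total_steps = 6e5, grid = grid,
                    x0 = -1, seed = s)
  run <- run_langevin_mtd(pot, cfg)
  fes <- reconstruct_fes(run$hills, grid)
  as.numeric(estimate_barrier(fes, list(c(-1.4, -0.6)), list(c(0.6, 1.4))))
})
aggregate_replicas(barriers)
#> <barrier_estimate> 3.31 +/- 0.24 kcal/mol (3 replicas)
```

Each replica deposits 1200 hills of 0.6 kJ/mol; the replica mean of
3.31 kcal/mol (13.84 kJ/mol) recovers the analytic 12.89 kJ/mol barrier
within the fluctuation expected of standard metadynamics, and the sd is the
reported uncertainty — the same protocol used for antiestrogen dissociation
barriers at the all-atom scale.

`autoplot()` methods render the DCCM, segment-score and per-residue-profile
tables and the reconstructed FES; `tidy()`/`glance()` methods summarize
clusterings, filters and barrier estimates. A thin CLI (`exec/ercoupler`)
exposes the same pipeline (`info`, `corr`, `cluster`, `hbonds`, `mtd`,
`screen`, `synth`, `run`) and `run_pipeline()` executes a YAML-configured
multi-stage analysis whose outputs carry the configuration hash for exact
reruns.

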