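---
title: "Methods: helix coupling, dissociation barriers and screening logic in ercoupler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: helix coupling, dissociation barriers and screening logic in ercoupler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ercoupler)
```

`ercoupler` packages the computational machinery used to characterize
activation and antiestrogen response of mutant estrogen-receptor-α (ERα)
ligand-binding domains from molecular-dynamics trajectories. This vignette
documents the models, the tunable parameters and their defaults, the
numerical choices, and — importantly — what the synthetic validation does and
does not establish about real trajectories.

## Covariance and cross-correlation (DCCM)

For two atoms the package computes the scalar (dot-product) covariance of
positional fluctuations,
$$C_{ij} = \langle (\vec r_i - \langle \vec r_i \rangle) \cdot
           (\vec r_j - \langle \vec r_j \rangle) \rangle \; [\mathrm{\AA^2}],$$
with the time average taken over the analysis window (divisor $N$, matching
the "average over the sampled period" reading). Normalization by the product
of the two standard deviations gives Pearson coefficients
$CC_{ij} \in [-1, 1]$: $+1$ is lockstep motion, $-1$ fully anti-correlated
motion. This is the scalar form, not the $3n \times 3n$ Cartesian covariance;
the eigen-decomposition of $C$ is exposed only as a descriptive summary
(`covariance_eigen()`), since no downstream analysis consumes the modes.

Assumptions and choices:

* **Atom selection.** The correlation is computed over one representative
  atom per residue; the default recommendation is Cα, the standard DCCM
  convention. The selection is an explicit argument, so all-heavy-atom or
  backbone variants are possible, but segment scoring *requires* one atom per
  residue and stops otherwise.
* **RMS fit first.** `rms_fit_trajectory()` superposes every frame onto the
  first over a fit selection (least squares, all atoms transformed), removing
  global rotation and translation; covariance is then computed in that frame.
  Degenerate (collinear) fit references are rejected. For dimers the fit is
  normally done on the whole dimer with per-monomer selections used in the
  scoring step.
* **No periodic-boundary handling.** Input trajectories are assumed
  whole-molecule imaged; unwrapping is the job of upstream MD tooling.
* **Zero-variance atoms** (fixed sites) cannot be normalized; their
  off-diagonal entries are set to 0 and their ids recorded on the result with
  a warning, rather than propagating NaN.

### Segment (helix) correlation scores

The coupling score between segments $I$ and $J$ sums $CC_{ij}$ over residue
pairs surviving the noise filter and divides by a correlation density:

* **Noise band.** Values $-0.6 < CC_{ij} < +0.6$ are discarded as
  uncorrelated noise. The band edges are included in the *kept* set
  ($|CC| \ge 0.6$): with an open discard interval, boundary values survive.
  The threshold is an argument (`threshold = 0.6` by default).
* **Density normalizer.** The surviving sum is divided by the product of the
  numbers of residues *contributing at least one surviving pair* — the
  literal reading of "residues contributing to the score". A variant
  normalizing by all residues of each segment is available
  (`density_normalizer = "all"`).
* A segment pair with no surviving residue pair scores exactly 0, and the
  table records the pair and residue counts so every score can be re-derived.

Per-residue profiles against a focus segment (typically H12) apply the same
filter before summation by default; passing `threshold = 0` gives the
unfiltered sum. Whether published profile figures filter first is not
deducible from their captions, so both modes are exposed; the default
matches the score convention for internal consistency.

## RMSD, clustering, hydrogen bonds

* `rmsd()` uses optimal least-squares superposition when `fit = TRUE`
  (delegated to bio3d) and keeps full numeric precision.
* `daura_cluster()` implements the greedy neighbor-count algorithm: the frame
  with the most neighbors within the cutoff (pairwise *fitted* RMSD) is
  extracted as a centroid together with its neighbors, and the process
  repeats on the remainder. The original formulation leaves ties open; here
  ties break toward the **lowest frame index**, which makes results
  deterministic and testable against an exhaustive oracle. Clusters are
  reported in decreasing size order.
* `hbond_occupancy()` counts a donor–H–acceptor triple as bonded when the
  donor–acceptor distance is ≤ 3.5 Å and the angle at the hydrogen is ≥ 120°
  — common MD practice; the source analyses never state geometric criteria,
  so these defaults are explicit arguments and every table records the
  criteria used. Covalent hydrogens are inferred by a ≤ 1.2 Å distance from
  the donor heavy atom in the first frame when bond records are absent.
  Occupancy (fraction of frames bonded) is reported as a continuous value;
  the package deliberately does not hard-code a "persistent vs transient"
  cutoff, since that label is never quantified in the literature it mirrors.

## Standard metadynamics on toy landscapes

The engine implements *standard* (fixed-height) metadynamics — constant
0.6 kJ/mol Gaussian hills at a fixed pace — not the well-tempered variant,
matching the reference dissociation protocol (hills every 4 ps at 310 K,
harmonic wall on the centre-of-mass distance at 3.5 nm). Collective
variables:

* **Coordination number** with the rational switch
  $s(r) = \frac{1 - (r/r_0)^n}{1 - (r/r_0)^m}$, defaults $n = 6$, $m = 12$
  (the common contact-counting exponents; the reference setup defers these
  to its MD plugin). The removable singularity at $r = r_0$ is evaluated as
  the analytic limit $n/m$, and the derivative limit $n(n-m)/(2m r_0)$ is
  used in chain-rule forces.
* **Centre-of-mass distance** between two groups, mass weighted, reported in
  nm (coordinates are Å; the 1 kcal = 4.184 kJ and Å/nm conversions are
  centralized).

Dynamics are integrated with BAOAB Langevin splitting. For the analytic
(direct-CV) potentials the compiled core accumulates the bias and its
gradient on a regular grid as hills are deposited (each hill touches only
grid points within 6σ) and interpolates the force linearly — per-step cost
independent of the hill count, the same strategy production codes use. The
host–guest tier instead computes CV gradients from particle coordinates via
the chain rule and is validated against finite differences.

Numerical and design choices:

* **FES estimator.** The surface is the negated bias of the *final* hill set,
  shifted to minimum 0 — no time-averaging over the last deposition window.
  The time-averaged estimator has lower variance but is deliberately not
  implemented, to keep one unambiguous estimator.
* **Barrier extraction.** "Inspecting two-dimensional FES plots" is made
  algorithmic as the lowest-saddle (minimax) path value between the two basin
  minima, computed exactly on the grid by a union-find sweep over cells in
  increasing FES order with 4-neighbour connectivity; the barrier is that
  saddle minus the bound-basin minimum, converted to kcal/mol. This is a
  declared convention, not something the reference text specifies.
* **Grid resolution.** A sensible default is σ/2 per CV; the validation runs
  use 881 points over [−2.2, 2.2] (spacing 0.005 = σ/20) so grid error is
  negligible against the method's intrinsic fluctuation.
* **Wall.** One-sided harmonic, energy $\kappa (s - s_0)^2$ above the wall
  with gradient $2\kappa(s - s_0)$; the force constant is never printed in
  the reference protocol, so it defaults to 1000 kJ/mol per CV-unit² and is
  configurable.
* **Determinism.** All thermostat noise is drawn in R from the configured
  seed and passed to the compiled core, so a config + seed reproduces the
  hill list, FES and barrier bit-for-bit.

### Validation conditions and what they show

The double-well benchmark uses $V(x) = h(x^2 - 1)^2$ with $h = 5\,k_BT$ at
310 K (12.89 kJ/mol), hill width 0.1 CV units, pace 500 steps of 0.005 ps
(2.5 ps), 6×10⁵ steps per replica (1200 hills), friction 5 ps⁻¹, unit mass —
sized so wells fill many times over and a replica runs in well under a
second. Across seeds the recovered barrier scatters with sd ≈ 1.3 kJ/mol and
a small positive bias (≈ +0.7 kJ/mol), both intrinsic to the final-hill-set
estimator of standard metadynamics; the acceptance check therefore averages
three seeds against a 15 % band. Replica uncertainty is reported as the
sample standard deviation of per-replica barriers, undefined for a single
replica.

The two-channel 2-D surface places basins at $(\pm 1, \pm 1)$ and channel
saddles of designed heights at $(0, \pm 1)$ (Gaussian channel profiles of
width 0.3 in $y$, quartic confinement $k_\mathrm{conf}(y^2-1)^2$ with
$k_\mathrm{conf}$ well above both saddles); the minimax barrier is
min(h₁, h₂) in closed form, and the extractor must pick the lower channel —
a direct test of saddle selection that a 1-D projection would fail.

## Virtual-screening logic

* **Property filter.** Lipinski's rule of five (MW ≤ 500 Da, HBD ≤ 5,
  HBA ≤ 10, logP ≤ 5) applied as a hard conjunctive filter — the funnel's
  purpose is eliminating poor-absorption compounds — plus the rotatable-bond
  cap (> 10 rejected). The "one violation allowed" Lipinski variant is
  selectable. Rejections are attributed to the first failing rule in the
  fixed order MW, HBD, HBA, LOGP, ROT, and tallies always sum to
  input − passing.
* **Consensus selection.** Docking scores are negative; "lower than the
  cutoff" is applied as ≤ (a strict-mode flag exists). "Favorable
  interactions" with a target conformation is operationalized as *a pose with
  a finite score exists for that target* (an empty cell means docking found
  no favorable pose) — the source never defines the phrase more precisely.
  The ligand-based protocol requires poses on ≥ 2 of the five conformations
  and ≥ 1 score within the −7.5 kcal/mol cutoff ("at least one", the weaker
  and more natural reading of an ambiguous clause). Every selection report is
  re-checked against its predicate before it is returned.
* **Ligand efficiency** is ΔG_b divided by the heavy-atom count; descriptor
  computation from structures is out of scope — the canonical input is a
  precomputed descriptor/score table, which keeps the module testable with no
  cheminformatics dependency.

## Synthetic data: scope of the evidence

Generators produce every input class with known ground truth:

* **Block-correlated trajectories** sample per-residue scalar displacements
  from a multivariate normal with the designed correlation matrix,
  independently for x, y, z, superposed on a rigid extended backbone. The
  dot-product covariance is then exactly 3σ² ρ and the target Pearson matrix
  is ρ itself, so recovery targets are exact. The implied correlation matrix
  is validated positive semi-definite (eigenvalue floor −1e-10) and the
  generator fails loudly rather than repairing a bad specification. Frames
  are generated in a fixed laboratory frame with no net rigid motion, so
  correlation recovery is assessed without fitting; fitting such a
  trajectory would absorb precisely the collective motion under study (the
  pipeline does this automatically for synthetic stages). The RMS-fit path
  is validated separately by the rigid-transform invariance property.
* **H-bond systems** place a collinear donor–H–acceptor triple inside the
  criteria in an exact, seeded subset of frames (at 80 % of the distance
  cutoff) and far outside otherwise, so occupancy has a designed value.
* **Compound tables** draw descriptors from ranges strictly inside or
  strictly outside each rule threshold with exact violator counts per rule.
* **Toy potentials** have closed-form barriers (double well: $h$;
  two-channel: min(h₁, h₂)) and gradients validated against central
  differences.

Passing these checks establishes that the estimators are implemented
correctly — that covariance, filtering, clustering, bias accumulation,
saddle search and the screening predicates do what their definitions say.
It does **not** establish force-field realism: the generators produce
isotropic Gaussian fluctuations, rigid backbones, literal H-bond geometries
and desk-scale landscapes, none of which exhibit the anharmonicity,
correlation between CVs, or slow orthogonal degrees of freedom of a solvated
95,000-atom receptor complex. Barriers from the toy engine validate the
machinery, not any biological number; protein-scale dissociation barriers
additionally carry the (unmodeled) error of CV choice.

## Known limitations

* Correlation is linear (Pearson) only — no mutual information, time-lagged
  correlation, or network analysis on the correlation graph.
* Standard metadynamics only: no well-tempered variant, multiple walkers,
  reweighting, or residence-time kinetics beyond the barrier itself.
* Docking, pose generation, MM-GBSA and descriptor calculation are upstream
  of this package; their outputs are consumed as tables.
* π-stacking and salt bridges are not detected; H-bond persistence is the
  only interaction statistic.
* Binary trajectory formats are out of scope; PDB multi-MODEL and multi-frame
  XYZ are the supported dialects (3-decimal round-trip precision).
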