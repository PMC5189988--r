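---
title: "Conformational-state analysis of two-lobe protein trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational-state analysis of two-lobe protein trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdstates)
```

## The problem

Many enzymes — the SMYD-family lysine methyltransferases are the motivating
case — consist of two lobes joined at a hinge. The substrate-binding crevice
sits between the lobes, so a clamshell-like opening motion converts a
binding-incapable ("closed", crystal-like) conformation into a
binding-capable ("open") one. Given an MD trajectory of such a protein,
`mdstates` answers four questions:

1. **Which conformational states does the trajectory visit, and when?**
   Cartesian PCA of the C-alpha coordinates, k-means segmentation in PC
   space, free-energy landscapes, and a hinge-axis (screw) decomposition of
   the inter-lobe motion.
2. **Which structural attributes define each state?** Per-frame hydrogen
   bonds, salt bridges, SASA, backbone dihedrals and distances, screened
   for correlation with the state labels.
3. **How does residue-residue coupling change over time?** The dynamic
   cross-correlation matrix (DCCM), its sliding-window generalisation
   (running cross-correlation, RCC), RCC deviation maps,
   distance-fluctuation maps, and a correlation-weighted dynamical network
   partitioned by Girvan-Newman community detection.
4. **Do the sampled conformers agree with solution scattering?** Debye
   theoretical curves, Guinier radius of gyration, pair-distance
   distributions P(r), and reduced chi-square fits per conformational state.

A synthetic two-state trajectory generator with exact ground truth stands in
for an MD engine so every stage of the pipeline can be validated end to end.

## The models and their assumptions

### State discovery

Frames are least-squares fitted (Kabsch superposition, proper rotation
enforced) to the first frame over the analysis selection; the 3N x 3N
covariance matrix of C-alpha coordinates is diagonalised, and frames are
projected onto the leading eigenvectors. k-means (k-means++ seeding, 25
restarts, fixed seed) partitions the projections; cluster quality is the
BSS/TSS fraction and the cluster count comes from the elbow of BSS/TSS
against k. Because the simulation starts from the closed crystal-like
structure, the cluster containing frame 1 is labelled *closed* (0). The
free-energy landscape is `-ln(rho/rho_max)` in kT over a 2-D histogram
(default 80 x 80 bins) of two PC projections; empty bins are reported as
`Inf` rather than a large number, and the global minimum is exactly 0 kT by
construction.

The hinge decomposition superposes conformer B on conformer A over the fixed
lobe, computes the optimal rigid transform of the mobile lobe between the
aligned pair, and splits it into a screw motion: rotation angle from the
trace of the rotation matrix, axis from its skew part (eigenvector route
near 180 degrees), axial translation as the projection of the translation
onto the axis, and an axis point from the perpendicular component. Rotations
below 1 degree leave the axis numerically undefined and are flagged rather
than reported.

### State-correlated attributes

Binary attributes (hydrogen bonds, salt bridges, contacts) are scored
against the 0/1 state labels with the phi coefficient; continuous attributes
(SASA, distances) with the point-biserial correlation; dihedrals are
sine-transformed first because they are circular. All three statistics are
Pearson correlations in disguise, which the test suite exploits as an exact
equivalence check. Attributes with |r| above a threshold (default 0.5, the
conventional screen level) are flagged, with the sign convention that
positive values mean "elevated or present in the open state". Group
differences use Welch's two-tailed t (states have unequal variances) for
linear data and the Watson-Williams high-concentration F test for circular
data, with the von Mises concentration estimated by the standard three-regime
inverse of A(kappa) and the validity warning issued below a mean resultant
length of 0.45. Raw statistics are reported without multiplicity correction
(a Benjamini-Hochberg column is emitted for transparency but not used for
flagging).

### Correlated motions

DCCM entries are normalised covariances of positional deviations. The RCC of
a residue pair is the same quantity computed inside a window of W frames
advanced one frame at a time and indexed by the window midpoint. Means are
recomputed **inside each window** (window-local centring): with global means
a pair whose coupling flips sign mid-trajectory averages to zero instead of
tracking the flip, so window-local centring is required for the analysis the
map exists for; the global-mean variant is available via the plain DCCM on
frame subsets. The RCC deviation map stores the standard deviation of each
pair's RCC series; pairs whose coupling changes (e.g. switching from
positive to negative at a state transition) attain the matrix maximum. The
default window is F/10 frames — long enough to smooth short-term
fluctuations, short enough to resolve a single transition — and is
configurable. Cost is O(R^2 F) via a sliding-sum kernel; beyond 1000
residues the function refuses and asks for a coarser node set.

### Dynamical network

One node per residue at its C-alpha; an edge joins residues whose heavy
atoms come within 4.5 Angstrom in at least 75% of frames ("at least" read
inclusively), excluding |delta resid| <= 1 sequence neighbours; edge weights
are `-log|C_ij|` so strong correlation means short graph distance.
Girvan-Newman removes the highest-betweenness edge (weights as path lengths;
deterministic lexicographic tie-break) and by default keeps the
maximum-modularity partition, with modularity computed on the unweighted
contact topology — using the same `-log|C|` values as both path lengths and
modularity strengths would conflate two opposite meanings of "weight".

A caveat discovered during validation and worth stating plainly: the
maximum-modularity partition of a geometric contact graph of a few hundred
residues essentially always subdivides a spatially extended domain, because
any lattice-like region has internal modularity substructure. Comparing
communities against a known two-domain architecture therefore uses the
dendrogram cut with exactly two communities (`n_communities = 2`), not the
modularity optimum; both are exposed.

### SAXS metrics

Theoretical curves use the Debye double sum with constant per-element form
factors (electron counts). Hydration-shell and excluded-volume corrections
of CRYSOL-class predictors are deliberately not modelled, so absolute
chi-square values against experimental curves of hydrated proteins are not
comparable with those predictors; the package's chi-square is meaningful for
*relative* comparisons (state A vs state B against the same curve) and for
internal consistency, which is what the per-state statistics use. P(r) is a
direct-space weighted histogram of pairwise distances (bin width 1.0
Angstrom by default) rather than a regularised inversion of the scattering
curve; its Fourier transform reproduces the Debye curve within 1% at bin
widths below 0.5 Angstrom, a property the tests assert. Guinier fits are
linear in ln I vs q^2 on the self-consistent range q*Rg <= 1.3 (the standard
validity limit) determined iteratively; non-negative slopes are an error,
not a number. The reduced chi-square uses the closed-form least-squares
scale factor and N-1 degrees of freedom.

## The synthetic generator

`generator_config()` defaults define the study conditions: two lobes of 100
residues each (poly-alanine-like backbone: N, CA, C, O and amide H per
residue, one chain, C-alpha lattice with 3.8 Angstrom spacing), an open
state produced by a rigid 25-degree rotation of lobe B about a hinge axis
(z through the origin) between the lobes, 2000 frames at 1-ps spacing, a
sharp single-frame transition at mid-trajectory (mirroring the sub-ns
transition such simulations show), and isotropic Gaussian coordinate noise
of 0.3 Angstrom — a magnitude typical of heavy-atom thermal fluctuation
about a state mean. Designed features give every downstream module a known
truth:

* three **state-specific contact pairs** across the lobes, placed at 3.0
  Angstrom (CA-CA) in the closed reference and 10.0 in the open one. The
  placement slides the lobe-B residue of each pair along the inter-CA
  direction, so these residues are the only deviation from the pure hinge
  rotation; hinge-recovery checks therefore exclude them, since the rigid
  ground truth does not apply to them by construction.
* the first contact pair doubles as a **correlation-switching pair**: both
  residues share a 0.5-Angstrom common displacement whose sign flips at the
  transition, so their cross-correlation is ~+0.7 in the closed state and
  ~-0.7 in the open state. Its RCC deviation should be (and is) the matrix
  maximum.
* one **designed psi dihedral** in lobe B resampled each frame from a von
  Mises distribution (kappa = 50) centred at -45 degrees (closed) or +120
  (open), implemented by rotating the successor residue about the CA-C bond
  to hit the drawn value exactly.
* the lobes are separated far enough (gap wider than the 4.5-Angstrom
  contact cutoff in both states) that only designed pairs bridge them, so
  the contact network's two-community structure is the lobe partition.

What the generator deliberately does **not** emulate: force-field energetics,
anisotropic or collective thermal motion (beyond the one designed pair),
solvent, side chains, gradual transitions (an optional linear interpolation
window exists for pathway-style experiments via per-frame construction),
and realistic SASA/H-bond chemistry. Passing recovery tests therefore
demonstrates that the estimators are correct and well-calibrated on data
satisfying their statistical assumptions — not that any particular real
trajectory will be as clean.

## Numerical choices

* Superposition: SVD-based Kabsch with determinant correction; degenerate
  (near-collinear) geometry warns and flags the result.
* Dihedrals follow the IUPAC sign convention (cross-checked against
  `bio3d::torsion.xyz`), range (-180, 180].
* Eigenvector signs are fixed (largest-magnitude component positive) so PCA
  output is reproducible across LAPACK builds.
* SASA sampling uses a deterministic Fibonacci sphere (default 960 points;
  a precision warning fires below 32). Points exactly on a neighbour's
  boundary (coincident spheres) are owned by the lower-index atom so shared
  surface is counted once.
* Distance-fluctuation maps use a two-pass variance: the one-pass form loses
  all significant digits on rigid geometries.
* k-means empty clusters are absorbed by restarting; an error is raised only
  when every restart fails.
* The Watson-Williams statistic is clamped at zero (the unclamped form can
  be marginally negative for identical samples through rounding).
* DCD files are written in the CHARMM single-precision dialect with the
  header timestep in ps, and read back including frame times; `bio3d`'s
  independent reader is used in the tests to validate the binary layout.

## Problem sizes

The validation suite runs the full default generator configuration (200
residues, 2000 frames) over five seeds for the end-to-end recovery checks,
and smaller configurations (8-50 residues per lobe, tens to hundreds of
frames) for per-module properties; calibration simulations use 1000 null
replicates for the two statistical tests and 100 replicates for the
chi-square self-fit. These sizes give every stochastic check a comfortable
margin at its threshold while keeping the whole suite at a few minutes on
one CPU.

## Known limitations

* Constant form factors mean absolute SAXS chi-square values are not
  comparable with hydration-aware predictors; only three structure-derived
  reference numbers (crystal-structure Rg, Dmax, inter-structure RMSD) are
  checked against published values, and those checks require the public PDB
  entries on disk.
* The hydrogen-bond detector requires explicit hydrogens by default; the
  heavy-atom fallback (donor-acceptor distance plus antecedent angle) is a
  clearly flagged approximation for crystal structures.
* `select_atoms()` implements a deliberately minimal grammar (name, resid,
  resname, chain, `and`); it is not a VMD-style expression language.
* Girvan-Newman is O(E^2 V) and intended for single-protein networks, not
  large complexes.

## A worked example

```{r example, eval = FALSE}
library(mdstates)

sim <- simulate_trajectory(generator_config(seed = 1))
traj <- sim$trajectory
ca <- atom_selection(sim$truth$ca_index)

fitted <- fit_trajectory(traj, ca)
pca <- fit_pca(fitted, ca)
proj <- project_pca(fitted, pca, ca, k = 2)
states <- kmeans_states(proj, n_clusters = 2, seed = 2)
states$bss_tss

screen <- screen_attributes(
  contact_screen_attributes(traj, sim$truth),
  states$labels)
head(screen)

net <- girvan_newman(build_network(traj, ca), n_communities = 2)
table(net$communities, sim$truth$lobe_assignment)
```
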