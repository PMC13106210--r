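---
title: "Trajectory analysis and hot-spot consensus: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory analysis and hot-spot consensus: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdhotspot)
```

mdhotspot implements the battery of analyses used to compare the stability
of apo and ligand-bound protein systems from molecular-dynamics
trajectories, and the consensus step that turns three independent streams
of evidence -- docking interaction occurrence, hydrogen-bond occupancy and
per-residue binding free-energy decomposition -- into a ranked list of
binding hot-spot residues. The motivating application is isoform-selective
inhibition of the sirtuin (SIRT) deacetylase family, where the question is
which binding-site residues distinguish one isoform's pocket from
another's; the machinery is generic for any protein--ligand system.

This vignette documents the models, conventions and numerical choices, and
what the package's planted-truth tests do and do not demonstrate.

## Structures, trajectories and units

Fixed-column PDB is the canonical structure format and multi-model PDB the
canonical trajectory format, so every analysis can be exercised from plain
text. Internally all lengths are in Angstrom; series summaries additionally
carry nm (or nm^2 for SASA) fields, because MD stability metrics are
conventionally reported as "(mean +/- sd) nm". The conversion happens only
at the reporting boundary. Van der Waals radii come from the Bondi set,
with unknown elements falling back to 1.70 Angstrom (carbon-like) with a
warning. Residues are keyed by (chain, residue number, residue name);
insertion codes are rejected rather than silently mishandled.

## Stability metrics

**RMSD.** Each frame is superposed onto the first frame (deviation from
initial positions) by the Kabsch algorithm -- SVD of the weighted
cross-covariance with the usual determinant-sign correction, so the
rotation is always proper (det = +1) and reflections are excluded. The fit
and measurement selection defaults to backbone atoms. Fewer than three fit
points, or a collinear/coincident fit set, is a degeneracy error rather
than a garbage answer.

**RMSF.** Per-residue fluctuation about the time-mean position, computed
after aligning every frame to the average structure (align to frame 1,
average, re-align to that average once -- the standard refinement). The
literature is split between average-structure and first-frame references;
the average-structure convention is used here because it makes RMSF the
standard deviation of a residue's position, and is what common MD toolchains
compute. This is a documented choice, not a claim about any particular
upstream tool.

**Radius of gyration.** Mass-weighted RMS distance from the centre of
mass, per frame.

**SASA.** Shrake-Rupley: each atom's sphere is expanded by the probe
radius (default 1.4 Angstrom, a water-sized probe) and sampled with
`n_points` (default 960) points from the deterministic golden-spiral
construction -- no RNG is involved, so SASA results are exactly
reproducible. A point is inaccessible if it falls inside any neighbour's
expanded sphere. Neighbour lists are radius-filtered all-pairs inside the
compiled kernel with early-exit occlusion; at the package's problem sizes
(up to a few thousand atoms) this is as fast as a cell grid and trivially
identical in results to the naive method. Hydrogens are excluded by
default (united-atom convention); at 960 points the single-sphere area is
within 1% of the analytic value and doubling the density changes results
by well under 0.5%. Probe radius and point density are documented defaults,
not claims of bit-compatibility with any specific SASA tool.

## Collective motions

**Essential-dynamics PCA.** The positional covariance of the selected
atoms (C-alpha by default) is diagonalised after superposing all frames
onto their average, and frames are projected onto PC1/PC2. The covariance
is unweighted (not mass-weighted): with a single-element C-alpha selection
mass weighting is a constant factor, and an unweighted matrix keeps mixed
selections simple; population covariance (divide by n_frames) is used so
that projection variance equals the eigenvalue exactly. Eigenvalues are
clamped at zero against roundoff.

**DCCM.** The dynamic cross-correlation matrix
C_ij = \<dr_i . dr_j\> / sqrt(\<dr_i^2\>\<dr_j^2\>) over frames, dr being
displacement from the time-mean position after superposition. A residue
with zero displacement variance would make the normalisation undefined;
its off-diagonal entries are reported as 0 (diagonal 1) with a warning.
The matrix is classified into percentage areas with strict thresholds:
correlated above +0.05, anti-correlated below -0.05, neutral in between --
boundary values are neutral by the strict-inequality reading. The
percentages are computed over *all* matrix elements including the
diagonal by default (so the correlated percentage is always at least
N/N^2); because it is not verifiable whether published percentage areas
included the diagonal, `classify_dccm(include_diagonal = FALSE)` provides
the off-diagonal-only variant.

Superposition before DCCM makes the result only approximately invariant
under frame reordering (the first-pass alignment reference is frame 1);
the residual is orders of magnitude below the classification threshold.

## Secondary structure

Backbone hydrogen bonds are scored with the Kabsch-Sander electrostatic
energy E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol
(distances floored at 0.5 Angstrom against numerical blow-up), a bond
existing when E < -0.5 kcal/mol. Amide hydrogens are constructed
geometrically when absent: 1.0 Angstrom from N along the bisector of the
N-C(prev) and N-CA directions. Chains are split into segments at chain
boundaries and at C(i)-N(i+1) distances over 2.5 Angstrom; no bond or
pattern crosses a break.

The supported alphabet is exactly seven classes -- alpha-helix (H), 3-10
helix (G), extended strand (E), isolated beta-bridge (B), turn (T), bend
(S, C-alpha direction change over i-2, i, i+2 greater than 70 degrees) and
coil (C) -- with precedence H > E > G > B > T > S > C. Pi-helix and
polyproline-II are not assigned separately (they fall into T/C). This is a
deliberate simplification: the goal is stable structured/unstructured
bookkeeping over trajectories, not bit-compatibility with any particular
DSSP binary.

The structured-residue (NSR) summary counts everything except coil as
structured and reports the initial count, the trajectory mean and standard
deviation, the change (mean minus initial; values near zero indicate a
stable system), and overall structured/coil percentages (which sum to 100
by construction).

## Conformational clustering

GROMOS (Daura) clustering on the all-pairs superposed RMSD matrix
(C-alpha by default, reported in nm): repeatedly take the frame with the
most neighbours within the cutoff (default 0.2 nm) as a centre, remove it
and its neighbours, repeat. Two conventions are pinned down because the
algorithm's common descriptions leave them open: the neighbour relation is
strict (`rmsd < cutoff`), and neighbour-count ties break towards the
lowest frame index. The summary triple -- number of clusters, first
cluster size, mean pairwise RMSD -- is what per-trajectory cluster
analyses conventionally report.

## Hydrogen bonds and occupancy

A bond is recorded when the donor-acceptor distance is at most 3.5
Angstrom and the D-H...A arrangement deviates from linearity by at most 30
degrees. Because the vertex of the 30-degree criterion is ambiguous in
common usage, the default measures the deviation at the hydrogen
(angle D-H-A >= 150 degrees, the VMD-style convention) and
`hbond_criteria(vertex = "donor")` switches to the donor-vertex reading.
Donors are N/O atoms with a hydrogen within covalent distance (1.2
Angstrom); acceptors are all N/O; same-residue pairs are excluded.

Atom-level occupancy is the percentage of frames a bond is present, in
[0, 100]. Residue-level occupancy is the *sum* of the atom-level
percentages between two residues -- the only aggregation consistent with
reporting residue occupancies above 100% when several atom pairs (or
main-chain and side-chain contacts) bond between the same residue pair --
so it is a per-residue bond-burden, not a probability.

## The consensus

Three residue sets are intersected by counting evidence:

* **Occurrence**: residues interacting with at least `floor(n/2)` of the
  `n` docked ligands, counting *distinct* ligands (several interaction
  classes with one ligand count once). The floor matters: published
  occurrence lists for 15-ligand sets include residues seen in 7 ligands
  (46.7%), so the inclusive `floor(n/2)` reading is the one that
  reproduces practice; a strict >= 50% rule would not.
* **Occupancy**: residues with residue-level H-bond occupancy of at least
  2% (the scale below which reported occupancies are conventionally left
  unlisted); configurable.
* **Energy**: residues with decomposition energy at or below -1 kcal/mol
  (a common favourable-contribution convention), or alternatively the
  top-k most favourable. The upstream producer of the energy table is
  expected to have restricted residues to the binding-site neighbourhood
  (typically within 4 Angstrom of the ligand); the package consumes, never
  computes, decomposition energies.

Residues are ranked by how many streams support them; at equal score,
residues supported by both occupancy and energy (the dynamics- and
energetics-based evidence) outrank those relying on the static docking
occurrence, then by occupancy percentage. This scoring is a documented
formalisation of how such short lists are merged in practice, not a claimed
reproduction of any particular published merge.

## Synthetic data: what is planted and what is not

The generators exist so that every analysis has a recovery test with a
known answer:

* `make_ideal_helix()` builds a poly-alanine N/CA/C/O backbone from
  canonical helical torsions (phi = -57, psi = -47 degrees); its interior
  i -> i+4 bonds score about -2.2 kcal/mol, comfortably past the -0.5
  threshold. `make_extended_chain()` (phi = psi = 180) is the negative
  control with no backbone bonds.
* `simulate_trajectory()` plants residue-residue correlation blocks: all
  residues of a block share one latent 3-D Gaussian factor per frame with
  loadings +1/-1, mixed with independent noise (`latent_weight`, default
  0.6, is the shared-variance fraction, giving block correlations of about
  +/-0.6 -- strong enough that at 2,000 frames essentially every planted
  entry has the planted sign). Displacements are applied rigidly per
  residue so C-alpha correlations equal all-atom correlations by
  construction. The displacement scale (sigma = 0.4-0.5 Angstrom per
  coordinate in the shipped test systems) produces RMSD/RMSF magnitudes
  of a few tenths of a nm, the scale typical of stable folded-protein
  trajectories.
* `simulate_hbond_trajectory()` draws each scheduled donor/acceptor pair
  bonded (2.9 Angstrom, 170 degrees) with the planted probability per
  frame, else broken (6.0 Angstrom); at 1,000 frames binomial sampling
  bounds the recovery error to about 1.4 percentage points (one sigma) at
  50% occupancy.
* `make_interaction_table()` / `make_energy_table()` plant exact
  occurrence counts and energy rankings.

All generators are pure functions of (spec, seed): identical inputs give
bit-identical outputs, and they save and restore the caller's RNG state.

What the planted tests do *not* show: the Gaussian factor model has no
force field, no solvent, no anharmonicity, no coupling between secondary
structure and the planted covariance, and the basin trajectories hop
uniformly rather than diffusively. Passing recovery tests demonstrates
that the estimators measure what they claim on data whose answer is known;
it does not validate any biological conclusion drawn from real
trajectories.

## Orchestration and problem sizes

`run_suite()` runs every analysis with stage isolation (a failing stage is
recorded as an error string; the rest still run, mirroring how the
analyses are reported independently) and serialises deterministically --
fixed numeric precision, no timestamps -- so identical inputs give
byte-identical JSON. `compare_systems()` orders systems per analysis by
the conventional stability directions (lower RMSD/RMSF/RG/SASA and PC1+PC2
spread, structured-residue change nearest zero, fewer clusters, larger
first cluster, more H-bonds) and records exact ties instead of breaking
them arbitrarily.

Default problem sizes in the shipped tests were chosen as the smallest
that make the statistics meaningful: 2,000 frames for sign-recovery and
variance-ratio tests (sampling error about 1/sqrt(2000) ~ 2%), 1,000
frames for occupancy recovery (binomial tolerance ~ 3 points), 200
residues for the end-to-end determinism run. SASA inside the suite is
evaluated on every 10th frame by default (`sasa_stride`) since it is the
most expensive per-frame analysis and its trajectory mean converges long
before frame-level sampling; the stride is a config knob, and stride 1
reproduces the dense series.

## Known limitations

* No periodic-boundary unwrapping: synthetic and prepared inputs are
  assumed whole. No mmCIF, altloc or insertion-code support.
* The secondary-structure assigner is a simplified DSSP as described
  above.
* Binary trajectory formats are out of scope natively; convert to
  multi-model PDB, or read with an established trajectory reader and
  construct an `md_trajectory` from the coordinate array.
* The consensus stage consumes interaction and energy tables; producing
  them (docking, MM/PBSA) is upstream of this package.
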