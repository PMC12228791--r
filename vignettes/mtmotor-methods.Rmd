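---
title: "mtmotor: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mtmotor: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtmotor)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The filament consensus model

A microtubule is a pseudo-helical polymer: N protofilaments of αβ-tubulin
dimers related by a per-subunit twist (−360/N degrees) and rise (~9.46 Å),
with a single seam that breaks the helical symmetry. Helical particle
metadata therefore carries two kinds of error that per-segment refinement
cannot resolve alone: incoherent in-plane parameters along a filament that
is physically continuous, and a 2N-fold ambiguity in the azimuthal angle φ
(N seam positions, each with a one-monomer (~41 Å) axial translation that
swaps the αβ register).

The consensus stage assumes filaments are *locally smooth*: orientation
and shift vary slowly along a filament, so a segment disagreeing sharply
with its neighbours is misaligned, not real. Operations and defaults:

* `modal_class_vote()` — the most frequent 3D class among a filament's
  segments overwrites all of them. Ties break to the smallest class id,
  a deterministic rule chosen because the upstream convention is unstated.
* `smooth_inplane(window = 5, outlier_threshold = 8)` — per filament and
  per column, a running median (circular for ψ, plain for shifts) flags
  values deviating by more than the threshold (degrees for ψ, Å for
  shifts) and replaces them; a centred moving mean (circular for ψ) of
  width `window` then smooths the cleaned series. `window = 5` and
  threshold 8°/8 Å are package defaults sized so that a single misaligned
  segment in an otherwise smooth filament is always corrected; both are
  configurable because the original smoothing kernel is not public.
  The moving-mean window shrinks *symmetrically* at filament ends, which
  makes any locally linear series an exact fixed point everywhere — with
  asymmetric truncation the ends would be biased toward the interior.
* `assign_phi_median()` — the circular median (the data value minimising
  summed circular distance; ties to the smaller angle) of a filament's φ
  is assigned to all its segments. A circular rather than linear median is
  used because φ lives on the circle and filaments can straddle ±180°.
* `segment_average(partners = 7)` — each segment's signal is averaged with
  its 7 adjacent partners: the consecutive window of 8 segments containing
  the target, centred with the extra partner on the high-index side and
  shifted inward at filament ends (filaments shorter than 8 use all
  segments). The high-side convention is the package's tie rule; with a
  window this wide the choice moves single-segment averages by one
  neighbour at most.
* `enumerate_seam_references()` / `assign_seam_register()` — hypothesis k
  in [0, N) applies Δφ = k·twist with Δz = k·rise; hypothesis k+N adds one
  monomer repeat axially. Register votes over the 2N classes are reduced
  per filament by the same modal rule, and the winning transform is
  applied to φ and, through each row's pose matrix, to the in-plane
  origins.
* `symmetry_expand()` / `subparticle_coords()` — poses map reference
  coordinates r to image coordinates x = A(rot, tilt, ψ)·r + t, with A the
  ZYZ Euler matrix. Lattice operators (rotate j·twist about z, translate
  j·rise along z) compose on the right; because the convention is ZYZ the
  rotation folds into rot exactly and only the projected axial offset
  touches the origins. Focused re-centering adds the in-plane projection
  of the rotated focus offset and is exactly invertible; the axial
  component of the rotated offset never moves the 2D origins.

Lattice defaults (`helical_lattice`): rise 9.46 Å, twist −360/N°, dimer
repeat 82 Å with monomer repeat 41 Å. These are the standard 13-pf
3-start B-lattice values; only the 82 Å box/dimer spacing is taken as an
input convention, the rest are textbook geometry and all are overridable.

## 2. Structure comparison

`superpose()` solves the least-squares rigid superposition (Kabsch, SVD
with reflection guard) over atoms paired by (chain, residue number, atom
name) — pairing by number, not name, because chimeric constructs keep the
parent numbering, so residue-name mismatches are tolerated. Cα is the
default atom subset both for alignment and scoring; the published global
RMSD values in this field rarely state their atom subset, which is why the
subset is configurable and recorded in the result object.

The default alignment frame `"PLOOP_A2A"` is residues 85–100 (P-loop
G85–T92 plus helix α2a through residue 100, human Kif5b numbering). The
exact range is a package decision — the elements are named in the
literature but never as residue intervals — and all named selections are
plain residue-number sets that can be replaced per species.

`rotation_between_heads()` aligns anchor heads first, then decomposes the
residual distal-head transform. The rotation angle uses the atan2 of the
antisymmetric part rather than acos of the trace: acos is ill-conditioned
near 0°, and identity comparisons would otherwise report ~0.01° of noise.
Angles below 1e-6° flag the axis as undefined.

`hbond_network()` works on H-free models, so the default criterion is
heavy-atom: donor–acceptor ≤ 3.5 Å and antecedent–donor–acceptor angle
≥ 90°. (With explicit hydrogens a D–H···A ≥ 120° criterion would be the
norm; cryo-EM depositions have no H.) Salt-bridge pairs (Lys/Arg/His
versus Asp/Glu/phosphate) use the distance criterion only, since their
geometry is not directional in the same sense. The chemistry table covers
the 20 amino acids plus ADP; unknown residues are skipped with a warning
rather than an error so a stray ion does not abort a comparison.
`network_diff()` keys on residue-pair labels, which makes the diff robust
to which copy of a bifurcated contact satisfied the criterion.

## 3. MD observables and the adaptive protocol

The ligand-stability reaction coordinates are the distances from the ADP
β-phosphorus to P-loop residues T87, S88, S89, K91, plus a fifth pair
involving E199. The public record is internally inconsistent about the
fifth pair's partner (S88 in one place, S98 in another), so
`default_monitored_pairs()` ships both presets and asserts neither.

`ligand_rmsd_series()` superposes each frame's core Cα set (default
residues 75–95) onto the reference frame and then measures ligand RMSD
*without* fitting the ligand: global rigid motion cancels exactly (tested
to 1e-9 Å) while genuine ligand motion relative to the core is retained.

`select_restart_frames()` implements the adaptive seeding selector. The
"combined value" of RMSD and distance deviation has no published formula;
the package defines score(t) = z(RMSD(t)) + mean over pairs of
z(|d(t) − d(0)|), z-scored per replica. z-scoring is the design choice
that makes Å-scale observables commensurate and renders the selection
invariant to affine rescaling of any single observable (a tested
property). Deviations are aggregated across the five pairs by *mean*
(max and sum were the alternatives; the mean keeps the two score terms on
the same scale). Ties go to the earlier frame. k = 2 reproduces the
Level-1→2 seeding; k = 7 from the pooled Level-2 data reproduces
Level-2→3, pooling being the package's reading of an unstated detail.

`detect_release(threshold = 20, dwell = 100)` declares a release at the
first frame where ligand RMSD stays above the threshold for `dwell`
consecutive frames and never again drops below threshold/2 — the
half-threshold return guard distinguishes committed escapes from
transient excursions. The published observation is qualitative ("complete
detachment with release into the bulk"), so the defaults are sized for
that regime: 20 Å is far outside any rebinding distance, and 100 frames
suppresses single-frame noise. The synthetic tests use smaller values
scaled to the toy well (threshold 15 Å, dwell 50) for speed.

`sim_time_ledger(adaptive_seeding_plan())` evaluates the three-level plan
— 1 seed × 3 replicas × 1000 ns, 2 × 5 × 150 ns, 7 × 5 × 150 ns — to
9.75 μs total.

## 4. What the synthetic generators emulate — and what they do not

`make_filament_table()` states this world: per-filament *quadratic* drift
in ψ, φ and shifts (slowly bending filaments, the smoothness assumption
the consensus stage relies on), additive Gaussian noise, a fraction of
outlier segments whose values are *replaced* by uniform draws of stated
half-width (a misalignment to a wrong lattice site replaces the estimate
rather than perturbing it), and register votes drawn i.i.d. from the
confusion row of the filament's true register. Coefficient ranges
(|linear| ≤ 1°/segment, |quadratic| ≤ 0.02°/segment² for ψ; half of that
for φ; shifts within ±20 Å drifting ≤ 1 Å/segment) were chosen once as
realistic for gently curved microtubules in ice and are not revisited.
What it does **not** emulate: images or volumes (votes stand in for 3D
classification), correlated noise along the filament, CTF, or filament
crossings. A green register-recovery test therefore establishes that the
consensus bookkeeping is correct under its stated vote model, not that
any classifier achieves 60% accuracy on images.

One honest subtlety: with quadratic truth the moving mean has a small
systematic bias (≤ |a₂|·h(h+1)/3 ≈ 0.04° at the defaults), so "smoothing
leaves clean data untouched" is exact only for locally linear series;
the invariant suite tests exact fixed-pointness on linear drifts and
strict error reduction on noisy quadratics.

`make_toy_structure_pair()` constructs the superposition ground truth in
reverse: mobile = T⁻¹(reference), with stated displacements applied after
the rigid transform so that alignment on the undisplaced residues
recovers the displacement magnitudes exactly. `make_escape_trajectory()`
integrates overdamped 3D Langevin dynamics in a flat-bottomed
harmonic-capped well (depth 8 kT, radius 10 Å, spring k = 2·depth/r²,
noise scale 1, dt 0.05, 5000 frames by default): with zero bias the
distance series is a stationary Ornstein-Uhlenbeck-like process; once the
outward bias exceeds k·r (1.6 at defaults) escape is drift-dominated and
the distance grows without bound. It is a caricature of nucleotide
release — no pocket chemistry, no ions, no compensatory network — built
to give release detection and the bias-monotonicity property a known
answer, not to estimate rates.

## 5. Degenerate inputs and numerical choices

* Angles live in [−180, 180); wraparound is applied after noise addition
  and after every composition.
* Superposition refuses < 3 pairs or collinear sets (second singular
  value < 1e-6) rather than returning an ill-defined transform.
* Constant observables z-score to 0 rather than NaN, so flat series fall
  back to the tie rule (earliest frames).
* `distance_fluctuation_sd()` errors on single-frame series; s.e.m. is
  the across-replica SD of per-replica SDs divided by √n, and is NA for a
  single replica rather than a misleading 0.
* Empty inputs: `occupancy_stats()` and `density2d()` error;
  `hbond_network()` on an empty model returns an empty network (a model
  with no atoms is a valid comparison operand, an empty population is
  not a valid denominator).

## 6. Known limitations

* The comparisons against deposited accession models (global RMSDs of
  0.2–0.5 Å between motor states, the ~3 Å and ~6.5 Å switch-region
  displacements, the ~14°/21° inter-head rotations) require fetching
  PDB entries and are therefore not reproducible in an offline test run.
  The identical code paths are validated on constructed ground truth with
  tolerances 10- to 1000-fold tighter than those comparisons would need;
  the residue-range and atom-subset ambiguities that would dominate such
  comparisons are documented above.
* The package performs no image processing: 3D classification and
  refinement results enter as metadata, which is exactly the boundary at
  which the consensus bookkeeping operates in production pipelines.
* Occupancy statistics summarise labels that an upstream classifier must
  provide; the one-/two-headed percentages of a real dataset are not
  recomputable from metadata alone.
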