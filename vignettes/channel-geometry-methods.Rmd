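---
title: "Quantifying conformational change in tetrameric ion channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying conformational change in tetrameric ion channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(channelgeom)
```

## Scope and model

channelgeom quantifies the geometry of tetrameric ligand-gated ion
channels — the package was built around the GluK2/K5 kainate-receptor
heteromer, whose four subunits occupy positions A–D with the pore-proximal
A/C pair (GluK5) and pore-distal B/D pair (GluK2) — and the differences
between two conformational states of one channel (for instance an
antagonist-bound, closed-cleft state versus a desensitized, agonist-bound
state). Five families of measurements are implemented:

1. **Pore-radius profiling** with constriction calling and residue
   attribution;
2. **Cross-pair symmetry RMSD**: how closely one diagonal subunit pair
   reproduces the other under a single rigid-body move;
3. **LBD centre-of-mass geometry**: within-dimer and between-dimer
   distances of the ligand-binding-domain layer;
4. **Angle decomposition** of inter-state domain motion: in-plane
   rotation, out-of-plane tilt, and clamshell cleft closure;
5. **Per-residue linker profiles**: lateral and vertical deviation over
   the M3-through-E-helix window, with divergence-residue detection.

All geometry runs on C-alpha atoms by default. Cryo-EM models of these
receptors are commonly built as poly-alanine outside the well-resolved
bundle crossing, so mass-weighted all-atom measures would be biased toward
regions with modeled side chains; uniform C-alpha weighting treats every
residue equally. Mass weighting remains available for complete models.

## The channel frame: what "vertical" and "lateral" mean

Every directional quantity is expressed in a channel frame with +z along
the pore axis toward the extracellular side and z = 0 at the pooled
M3-bundle C-alpha centroid. The pore axis is computed as the normalized
mean of the per-chain M3 helix axes (each the first principal direction of
that chain's M3 C-alpha set, oriented along increasing residue number).
A single pooled principal direction was considered and rejected: in a wide
bundle the lateral spread across chains can rival the axial extent, and
the pooled first principal direction then flips into the membrane plane
without warning. Per-chain axes are immune to this because each M3 helix
is individually elongated along the pore. If any chain's top two singular
values agree within 1%, the axis is declared degenerate and an explicit
`channel_frame()` is required rather than silently picking a direction.

The frame's sign is fixed by requiring the LBD layer at positive z, and
the x axis is the in-plane projection of the A-position LBD centroid, so
the frame is deterministic and equivariant: rigidly moving the assembly
moves the frame with it, which the test suite verifies directly.

Two states are compared after one joint Kabsch superposition of their
four-chain M3-bundle C-alpha sets. This is justified by the observation
that the M3 helices change little between channel states relative to the
LBD layer; the residual M3 RMSD is always reported so a user can judge
whether the shared frame is adequate for their pair of models.

## Pore profiling

The profile reports, for each slice plane z, the radius of the largest
sphere centred in that plane touching no atom:

r(z) = max over in-plane centres c of min over atoms i of (‖c − aᵢ‖ − vdwᵢ),

clamped to [0, max_probe]. Defaults: 0.5 Å slice step, 10 Å probe cap,
HOLE-style simple element radii (C 1.85, N 1.75, O 1.65, S 2.0, H 1.0 Å)
and a closed-channel cutoff of 1.15 Å — the radius below which a section
is treated as impassable to water. The vdW set is configurable and echoed
into every report.

The inner maximisation is solved per slice by Nelder–Mead started from
(a) the previous slice's centre (warm start, which couples slices the way
a probe sphere walks a pore), (b) the best point of a deterministic 1 Å
coarse scan of the search disc, and (c) eight seeded random restarts
within 5 Å. The search is constrained to a 10 Å disc about the axis
because an unconstrained search escapes sideways into lipid-facing
cavities. Slices with no atoms within max_probe + max(vdW) of the plane
are reported at the cap with a `bulk` flag rather than an error, keeping
profiles plottable end to end. The z = 0 convention is stated in every
exported profile because plotting conventions for "channel position"
differ between tools.

Constrictions are interior local minima (smallest sample within a ±2 Å
window; boundary samples excluded, so a monotone profile has none), below
a caller-chosen cutoff, with minima closer than 2 Å merged keeping the
smaller. Residue attribution ranks residues by minimum clearance to the
probe centre; in a four-chain channel the best residue per chain is
reported, and exact ties are all kept, ordered by chain and residue.

## Symmetry and angle conventions

The cross-pair symmetry RMSD pairs the B/D C-alpha atoms with A/C through
the residue correspondence (for GluK2/GluK5 the shipped default is the
constant −16 offset valid in the M3/E-helix region: 631↔615, 652↔636,
664↔648, 676↔660; outside that region a user-supplied map is required
because no global alignment is assumed), performs one joint rigid fit of
the two-chain body, and reports the minimised RMSD. Both pairing
orientations (B→A, D→C and B→C, D→A) are tried and the better one
reported — the deposited chain labelling of a new model is not assumed.

Angles follow fixed conventions, embedded in every report:

* **In-plane rotation** is the 2-D orthogonal least-squares rotation of
  the domain's xy-projected, centroid-centred C-alpha set between states,
  signed right-handed about +z, in (−180°, 180°].
* **Tilt** is the angle between the domain's first principal direction
  (oriented away from the membrane) and +z; the inter-state tilt change is
  the difference of the two states' values.
* **Cleft closure** superposes the two states on the D1 lobe and reports
  the rotation angle (from the rotation-matrix trace, with the argument
  clamped to [−1, 1]) of the residual fit carrying D2 of one state onto
  the other. It is independent of either state's global pose.

D1/D2 lobe boundaries and LBD residue intervals are deliberately not
defaulted: they are model-specific, the reports always print the intervals
used, and missing definitions cause that stage to be skipped by name
rather than silently guessed. Dimer pairing for COM distances defaults to
(A,B)+(C,D) — the heterodimer arrangement — and the between-dimer distance
is defined as the distance between the two dimer-COM midpoints, a
convention recorded in each report.

## Linker profiles and divergence detection

Lateral deviation is the in-plane (xy) distance between a residue's
C-alpha in the two states; vertical position is its z coordinate. A
full-3D displacement variant exists because "lateral motion" is sometimes
read as total displacement; the in-plane definition is the primary one.
Gaps (unmodeled residues) are omitted and listed, never interpolated.

The divergence residue — where a subunit's linker stops tracking the
reference state — is detected by a rule with four exposed parameters: the
baseline is the median of the first 10 profile values; a residue diverges
if its value exceeds max(3 × baseline, 2 Å) and at least 3 subsequent
samples stay above that threshold. The persistence requirement makes
isolated spikes non-qualifying; the 2 Å floor keeps near-zero baselines
from tripping on noise. On rigid-rotation fixtures the deviation past the
breakpoint is a flat chord, not a growing ramp, which is why persistence
is defined as "staying above threshold" rather than monotone increase.
The first moved residue is breakpoint + 1, so recovery is accurate to one
residue by construction.

## The synthetic generators

Each analysis stage is validated against generators whose ground truth is
exact:

* `make_ideal_helix()` — textbook α-helix (1.5 Å rise, 100° twist, 2.3 Å
  C-alpha radius).
* `make_cn_bundle()` — exact Cn-symmetric helical bundles (templates
  replicated by 360°/n rotations), for symmetry RMSD and frame recovery.
* `make_pore_lattice()` — atom rings with analytic pore radius
  ring_radius − vdw at each ring plane. For a regular ring the on-axis
  centre is the exact maximiser (moving any direction shortens the
  distance to the nearest atom), so the discretization correction is
  exactly zero and recorded as such. A coplanar guard ring 5 Å outside
  each pore ring stands in for the protein wall: a bare ring floating in
  vacuum has its largest inscribed sphere outside the pore, which no real
  channel does.
* `make_clamshell_pair()` — two helical lobes with a controllable hinge
  angle about the inter-lobe boundary, in a seeded shared random pose.
* `make_state_pair()` — the study conditions. Four chains at positions
  A–D, each an analysis-window helix (residues 631–676, 9 Å from the
  axis) topped by a 20-residue LBD marker helix leaning away from the
  axis. The marker gives the mobile domain a realistic ~30 Å extent; a
  domain only a few residues long would make rotation estimation
  ill-conditioned in a way real LBDs (≈ 30 Å across) are not. State B
  rotates each chain's residues beyond the breakpoint about the channel
  axis and elevates them along it. The defaults encode the motions
  reported for GluK2/K5 desensitization: 18° at A/C, 110° at B/D, 12 Å
  elevation at B/D, breakpoint at residue 662. Noise is isotropic
  Gaussian per coordinate, applied to state B (state A is the exact
  reference), seeded and echoed in the ground truth.

What the generators do *not* emulate: side chains, sequence, sterics,
density-map error correlation along the chain, or partial occupancy.
Passing the synthetic suite therefore demonstrates correctness of the
geometry and the estimators' noise behaviour, not robustness to every
artefact of real model building; for real models the reported residual
RMSDs and the skipped-stage list are the relevant diagnostics.

## Numerical choices

* Superposition is closed-form Kabsch via SVD with the reflection branch
  forced to det = +1; fewer than 3 pairs or collinear points raise a
  rank-deficiency error. The test suite checks it against a brute-force
  quaternion search and against an independent implementation.
* Alt-locs resolve to the highest-occupancy conformer, ties to the
  alphabetically first id; missing occupancy is 1.0. Insertion codes are
  rejected with an error; negative residue numbers pass through. Author
  numbering is used everywhere, never renumbered.
* Angle magnitudes come from acos of the clamped trace expression; signed
  in-plane angles from atan2, so no branch ambiguity near 0° or 180°.
* Subunit-position inference requires ≥ 1 Å radial separation between
  the candidate proximal and distal pairs, otherwise an explicit mapping
  is demanded. Geometry cannot identify subunit *types*, so inferred
  proximal/distal types default to GluK5/GluK2 and are overridable.

## Problem sizes

The shipped validation suite runs entirely on synthetic assemblies:
10-point clouds for superposition oracles, 4 × 30-residue bundles for
symmetry, 200-atom toy channels against an exhaustive 0.05 Å grid oracle,
and 100 seeded state-pair replicates at 0.3 Å coordinate noise (264
C-alpha atoms per state) for the recovery criteria — rotations within 2°,
elevations within 0.5 Å, breakpoint within ±1 residue in at least 95% of
replicates. These sizes exercise every code path while keeping the whole
suite near twenty seconds.

## A worked example

```{r example}
sp <- make_state_pair(noise_sigma = 0.3, seed = 1)
cmp <- compare_states(sp$state_a, sp$state_b, sp$map, sp$scheme)
cmp
```

The in-plane rotations recover the generator's 18°/110° defaults, the
divergence residues sit one past the 662 breakpoint, and the cleft-closure
stage is reported as skipped because the synthetic scheme defines no
D1/D2 lobes.

## Known limitations

* The pore axis is held straight; a strongly curved permeation pathway
  (as full HOLE traces) would need a bent-axis extension.
* No conductance, electrostatics or solvation modelling.
* The cross-subunit correspondence ships only for the GluK2/GluK5
  M3/E-helix region; other pairings need a user map.
* Assembly symmetry operators in mmCIF are not expanded; the deposited
  coordinates are taken as the biological unit.
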