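---
title: "Descriptor methods for IgG1 Fc glycoform trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptor methods for IgG1 Fc glycoform trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcdyn)
```

# Scope and model

`fcdyn` quantifies, from a topology plus a coordinate trajectory, the
descriptors used to characterise how N-glycan composition shapes IgG1 Fc
structure and dynamics: glycan–protein association and detachment, the
conformational ensemble of the C′E loop (Gln295–Thr299) and of the
Asn297-linked GlcNAc1, the openness of the FcγRIIIa-binding interface
(D_AB), Cγ2–Cγ3 / Cγ3–Cγ3 orientation angles, the radius of gyration, and
a half-split convergence diagnostic. The package analyses trajectories; it
does not produce them, and it assumes the solute is whole (no periodic
re-imaging is performed — distances are computed on raw coordinates).

All residue numbers follow the structure file as-is (EU numbering for Fc:
N297, loop 295–299, anchors 259–265/301–306); no renumbering is ever
applied. Hydrogens are read and retained but every descriptor defaults to
heavy atoms only, so results do not depend on hydrogen placement.

# Geometry

Superposition uses the SVD form of the Kabsch algorithm with a determinant
correction that excludes reflections (chiral molecules must never be
mirror-fitted). The selection-based RMSD protocol computes the rigid fit
on a *fit selection* and applies that same transform to a *measure
selection*; the measured atoms never influence the fit. This mirrors the
standard anchored-loop protocol: fit on the Cα atoms of residues 259–265
and 301–306 of one chain, measure the heavy atoms of 295–299 (or of
GlcNAc1). Unit tests verify the fit against an independent
quaternion-eigenvalue (Horn) implementation to 10⁻⁶ Å and the rotation's
orthonormality to 10⁻¹⁰.

The dihedral sign follows the IUPAC convention (cis = 0°, trans = 180°,
range (−180°, 180°]); angles lie in [0°, 180°]. The radius of gyration is
mass-weighted over heavy atoms by default, with a uniform-weight option,
because the two conventions differ by roughly 0.1–0.3 Å in absolute terms
for proteins and published values rarely state the choice.

# Glycan association descriptors

The glycan is represented as a per-chain rooted tree using the
high-mannose residue numbering: GlcNAc1 (root, Asn297-linked) — GlcNAc2 —
β-mannose 3, one arm 4→(5→6, 7), the other 3→8→9→10. Terminal
(non-reducing end) sets per glycoform: Man8 {6, 7, 10}, Man5 {5, 7, 8},
single GlcNAc {1}; the aglycosylated form has no tree. Man5 is Man8 with
residues 6, 9 and 10 removed, so shared residues keep identical parents.

Three descriptors follow:

* the **terminal minimum-distance series** — per frame, the minimum over
  all heavy atoms of all terminal residues versus all protein heavy atoms.
  "Termini" means the terminal set, because those are the residues whose
  solvent exposure controls enzymatic remodelling;
* the **contact matrix** — one Boolean row per glycan residue, `TRUE` when
  that residue's minimum heavy-atom distance to the protein is ≤ 4.5 Å
  (default), summarised by `bound_fraction()`;
* **detachment events** — maximal runs of frames with terminal minimum
  distance > 9 Å (default), at a default minimum duration of one frame
  (240 ps at the default save interval) because sharp single-frame peaks
  are genuine excursions at that sampling rate. Detachment is defined on
  the combined terminal series, not per residue; per-residue behaviour is
  available through the contact matrix.

# Loop-state classification

Published analyses of the C′E loop distinguish *unstructured*,
*outward-facing* and *inward-facing* conformations qualitatively from
snapshots. `classify_loop_states()` operationalises this as a
deterministic decision rule evaluated per frame and chain:

1. compute the strand-order score: the fraction of expected antiparallel
   Cα pairs between the short C′ strand (default residues 290–294) and the
   E strand (default 304–308, paired in reverse) whose distance deviates
   from its reference pairing distance by at most `pair_tol` (6.5 Å). If
   the score is below `s_min` (0.5) the frame is **unstructured**;
2. otherwise, if the anchored loop RMSD is below `r_native` (3.0 Å) the
   frame is **native**;
3. otherwise the sign of the projection of the loop-centroid displacement
   (after the anchor fit) onto the inter-chain cavity axis decides:
   toward the opposing chain's Cγ2 centroid is **inward_facing**, away is
   **outward_facing**.

The distance-based pairing score was chosen over DSSP-style hydrogen-bond
assignment so classification does not depend on hydrogen placement, and
the C′/E strand ranges are configuration-declared because their exact
extent varies between structure annotations. `r_native = 3.0` Å sits
between reported native-like loop RMSDs (≈ 2.7–3.5 Å window averages) and
clearly deformed snapshots (≥ 6 Å); the rule reproduces the published
snapshot ordering — low-RMSD ordered-strand frames facing away from the
cavity are outward, high-RMSD ordered-strand frames toward the cavity are
inward, broken-strand frames are unstructured regardless of RMSD. The
classification is piecewise-constant in its evidence, so sub-threshold
coordinate perturbations never change a label (verified by test).

Window summaries report the arithmetic mean and *population* SD — the
convention for trajectory statistics; at thousands of frames the
difference from the sample SD is negligible. The default window is the
trailing 75 % of the time span, generalising the common "last 1.5 μs of a
2 μs run" convention to trajectories of any length.

# Domain orientation and interface geometry

Interface residue sets may be assigned from a complex structure
(`assign_interface_residues()`: Fc residues with any heavy atom within
4.5 Å of any receptor heavy atom — the same cutoff as glycan contacts,
since no separate value is established) or declared in the config. D_AB is
the distance between the two sets' heavy-atom geometric centers.

θ/φ anchor points default to, per domain, the Cα geometric centers of the
domain's N-terminal and C-terminal halves (Cγ2 = 238–340, Cγ3 = 341–443,
EU convention; both configurable). This is a documented stand-in
convention: published anchor definitions exist but their exact selections
are not reproducible from available text, so the package exposes the
general four-selection interface and defaults to the halves construction,
which is deterministic, chain-symmetric and robust to missing residues.
Histograms use fixed-width bins anchored at 0 (defaults 1 Å / 2°) so
distributions from different runs share bin edges; refinement and
normalisation invariants are tested.

The convergence check splits a series at the midpoint frame and compares
half means; the default tolerance of 0.5 Å suits RMSD-type series. A
planted linear 0→5 Å ramp has a half-mean difference of exactly 2.5 Å
(when sampled at midpoints) and must fail; stationary noise must pass.

# The synthetic generator: what it emulates, and what it does not

Because suitable long Fc trajectories are not generally redistributable,
every descriptor is validated against synthetic trajectories with planted
ground truth. The generator builds a two-chain bead model — one carbon
"Cα" bead per residue, residues 238–443 per chain arranged as two
12-Å-radius domain shells, with an explicit antiparallel strand pair
(290–294/304–308, 4.8 Å pairing distance), a five-bead loop (295–299)
bridging them, and a branched glycan of single-bead residues rooted
1.45 Å from bead 297. Bead residues reuse Fc numbering so all production
code paths run unchanged.

Per frame, the generator plants:

* **orientation**: each chain's Cγ2 domain is rigidly re-oriented so that
  the four anchor centers realise θ and φ drawn from declared Gaussians
  (φ wrapped). Defaults θ ~ N(85°, 6°), φ ~ N(−17°, 12°) place roughly
  ±3 sd over the spans reported for intra-chain Cγ2–Cγ3 motion
  (θ ≈ 68–104°, φ ≈ −51–18°); the Cγ3 domains stay fixed, making the
  inter-chain Cγ3–Cγ3 pair nearly rigid, as observed. Placement uses
  internal-coordinate (NeRF) construction followed by the minimal rotation
  mapping the reference anchor arm onto its target, so noise-free frames
  reproduce the drawn angles exactly (tested to 10⁻⁸ deg);
* **loop state** from a declared schedule (default 40 % native, 20 % each
  outward/inward/unstructured): inward/outward displace the loop beads by
  ±6 Å (2 × `r_native`) along the cavity axis; unstructured breaks the
  strand pairing by a 9 Å shift of the C′ beads (pairing deviation well
  past `pair_tol`) and scatters the loop beads 6–9 Å tangentially to the
  domain surface. Tangential scatter keeps even the most displaced loop
  bead clear of detached glycan residues, which sit far out along the
  surface normal;
* **glycan kinetics**: a two-state Markov chain per chain (default
  bound→unbound 0.02, unbound→bound 0.9 per frame; stationary unbound
  fraction p_d/(p_d+p_a) ≈ 0.022). Detachment is rare and, at a 240 ps
  frame interval, lasts of the order of one frame — matching the
  phenomenology of sharp single-frame minimum-distance peaks. The near-1
  reattachment probability also keeps successive frames nearly
  independent, so the binomial sampling bound used in the stationary-
  distribution check is calibrated. During unbound intervals all residues
  except the covalently anchored GlcNAc1 move 15 Å along their surface
  normals, guaranteeing terminal distances far above the 9 Å threshold
  (bound geometry sits ≈ 2–3.5 Å from the surface, far below it);
* **noise**: isotropic Gaussian per-coordinate noise, default sd 0.2 Å —
  an order of magnitude below every planted margin.

Everything is deterministic given the spec's single seed (R's default
Mersenne-Twister stream; no time- or platform-dependent state).

The generator reproduces the *statistical structure* the descriptors must
resolve, not biophysics: there is no force field, no excluded volume, no
solvent, no correlation between loop state and glycan state, and bead
residues have one atom. Consequently, passing recovery tests demonstrates
that the descriptor and classifier code measures what it claims under
realistic noise — it does not validate any biological conclusion about
real Fc glycoforms, and the package makes no claim to reproduce published
trajectory statistics, which would require the original multi-microsecond
trajectories.

# Problem sizes and numerical choices

The validation suite uses: 100 random 50-point instances for the
superposition oracle and 200 instances (30×40 points) for the
minimum-distance oracle; 20 seeded 5000-frame trajectories for
detachment recovery (frame-level precision and recall); 10 seeded
1000-frame trajectories for loop-state recovery; 5000 frames for θ/φ
moment recovery and for the Markov stationary check. These sizes give
sampling errors comfortably below the asserted bounds (e.g. the sd of a
5000-sample Gaussian sd estimate is ≈ 1 % relative).

Degenerate inputs are rejected rather than silently handled: collinear
fit selections, empty selections, zero-length angle arms, non-positive Rg
weights, too-short convergence series, and windows that miss the series
all raise errors naming the offending quantity. Altloc records keep the
highest occupancy (ties: first in file); insertion codes are folded into
the residue key. Trajectory containers store no times, so frame times are
`frame_dt_ns` × frame index (default 0.24 ns, a 240 ps save interval),
overridable in the config.

# Known limitations

* No periodic-boundary handling: trajectories must contain a whole,
  un-wrapped solute.
* The θ/φ anchor defaults are a documented stand-in convention; absolute
  angle values are comparable only within a fixed anchor definition.
* `read_pdb()` targets PDB-format files (one model for topologies);
  mmCIF is out of scope, as is any force-field or bond-topology parsing
  beyond the declared glycan tree.
* The chain A/B labelling of a deposited structure relative to the
  analysis convention is not knowable from coordinates alone; the config
  declares it.
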