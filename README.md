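# fcdyn

Trajectory descriptor analysis for IgG1 Fc glycoform simulations.

The crystallizable fragment (Fc) of IgG1 is a homodimer of Cγ2–Cγ3 domain
pairs carrying an N-glycan at Asn297, and its binding to Fcγ receptors —
hence antibody effector function — depends on the glycan's composition.
Molecular-dynamics simulations of Fc glycoforms (high-mannose Man8/Man5,
single-GlcNAc, aglycosylated N297Q) are commonly analysed through a small
set of geometric descriptors. `fcdyn` implements that descriptor pipeline
as a tested, reusable R package for structural bioinformaticians working
on Fc engineering:

- **Glycan–protein association** — per-frame minimum distance between any
  heavy atom of the glycan *terminal* residues and any protein heavy atom;
  a residue-by-frame contact matrix at a 4.5 Å heavy-atom cutoff; and
  detachment events, defined as maximal runs of frames whose terminal
  minimum distance exceeds 9 Å.
- **C′E loop conformational ensemble** — the loop Gln295–Thr299 carries the
  glycosylation site and forms part of the FcγRIIIa interface. Its RMSD
  series uses the anchored protocol: superpose each frame onto the
  reference using Cα atoms of residues 259–265 and 301–306 of the same
  chain, then measure all heavy atoms of residues 295–299 (never re-fit on
  the measured atoms). The same protocol yields the GlcNAc1 RMSD series. A
  deterministic three-way rule classifies each frame as `unstructured`
  (C′-strand pairing score below `s_min`), `native` (loop RMSD below
  `r_native`), or `inward_facing` / `outward_facing` by the sign of the
  loop-centroid displacement projected on the inter-chain cavity axis.
- **Global conformation** — D_AB, the distance between the geometric
  centers of the receptor-interface residue sets of the two chains;
  Cγ2–Cγ3 and Cγ3–Cγ3 orientation angles θ = angle(P1,P2,P3) and
  φ = dihedral(P1,P2,P3,P4) over four Cα anchor centers; mass-weighted
  radius of gyration; normalised fixed-grid histograms; and a first-half /
  second-half convergence check.
- **Synthetic trajectories with planted ground truth** — a bead-model Fc
  generator (`synthetic_spec()`, `generate_trajectory()`,
  `write_fixture()`) plants loop-state schedules, two-state (bound/unbound)
  glycan Markov kinetics and Gaussian θ/φ orientation distributions, so
  every descriptor and the classifier are validated against known answers
  without any external data.

Structures are read from PDB, trajectories from multi-model PDB or
CHARMM/NAMD DCD (readers built on `bio3d`); all geometry
(Kabsch superposition, selection-based RMSD, distances, angles, dihedrals,
Rg) is implemented and unit-tested in the package.

## Worked example

Generate a Man8-like synthetic fixture and run the full pipeline:

```r
library(fcdyn)

spec  <- synthetic_spec(seed = 11, n_frames = 500)
paths <- write_fixture(spec, "man8_fixture")

cfg <- run_config(topology = paths$system, trajectory = paths$trajectory,
                  glycoform = "Man8", out_dir = "man8_out")
rep <- run_all(cfg)

rep$glycan$chains$A$n_events                    # 10
rep$glycan$chains$A$bound_fraction[["1"]]       # 1
rep$loop$chains$A$loop_rmsd_summary$formatted   # "5.30 ± 2.57 A"
unlist(rep$loop$chains$A$state_fractions)
#  inward_facing         native outward_facing   unstructured
#            0.2            0.4            0.2            0.2
rep$domains$d_ab_summary$formatted              # "73.15 ± 4.24 A"
rep$domains$rg_summary$formatted                # "30.73 ± 0.18 A"
rep$domains$angle_summaries$cg2_cg3_A$theta$formatted
# "86.14 ± 6.77 deg"
```

Reading the output: chain A's glycan detached 10 times (terminal minimum
distance > 9 Å); its anchor-linked GlcNAc1 never lost protein contact
(bound fraction 1, as it is covalently anchored at Asn297); the loop-state
fractions recover the planted 40/20/20/20 schedule exactly; and the
Cγ2–Cγ3 angle summary recovers the planted Gaussian (mean 85°, sd 6°)
within sampling error. The per-frame series, contact matrices, histograms
and the aggregated `report.json` land in `man8_out/`. Note the loop-RMSD
convergence flag is `FALSE` for this fixture — the planted schedule is
segmented in time, so the two trajectory halves genuinely differ; a
stationary series passes.

The same functions run on real data: `read_pdb()` +
`read_trajectory()` accept any topology/trajectory pair whose chains
follow Fc (EU) residue numbering, with every residue range and threshold
overridable through `run_config()` / `loop_config()` or a flat key-value
config file (see `inst/extdata/example_run.cfg` and the CLI wrapper
`inst/scripts/fcdyn.R`).

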