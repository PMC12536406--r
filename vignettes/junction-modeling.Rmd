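---
title: "Modeling heteromeric amyloid junctions with crossbeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling heteromeric amyloid junctions with crossbeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossbeta)
```

## The modeling problem

Amyloid fibrils are built from peptide chains stacked in parallel,
in-register β-sheets along the fibril axis, with a characteristic
inter-strand rise of about 4.8 Å. Two different amyloidogenic peptides can
cross-seed: a fibril of peptide A can template elongation by peptide B.
Structurally, the simplest hypothesis for such axial cross-interaction is a
*heteromeric junction*: a single interface where the terminal chain of the
A-stack hydrogen-bonds to the first chain of the B-stack, with each chain
otherwise retaining its homomeric fold.

`crossbeta` implements a three-stage workflow for building and scoring such
junction models, using the amyloid-β(1–42) / islet amyloid polypeptide
(IAPP) pair as the worked case:

1. **Template selection** — choose which experimental fibril polymorphs of
   the two peptides are geometrically most compatible at the junction.
2. **Biased refinement** — assemble the two stacks, impose β-sheet-like
   distance restraints across every interface (including the heteromeric
   one) and graded shape restraints that preserve each chain's fold, then
   relax and sample the restrained system.
3. **Analysis** — quantify junction quality: hydrogen-bond occupancy,
   contact probability, β content, conformational clustering, and a
   residue-pairwise decomposition of polar and nonpolar interchain
   energetics.

## Residue correspondence and regions

The two peptides are paired by a *gapless* alignment: a constant register
offset between residue numbers, chosen so that the hydrophobic cores
coincide. For the worked case the offset is 5 (Aβ residue *i* pairs with
IAPP residue *i* − 5; e.g. Aβ 15 ↔ IAPP 10). `region_spec()` exposes the
residue windows used at each stage:

```{r regions}
region_spec("template")   # template-pair ranking window
region_spec("restraint")  # junction restraint window (34 pairs)
region_spec("analysis")   # occupancy / contact reporting window
region_spec("polymorph")  # common core for polymorph comparison
```

The windows differ on purpose. Template ranking uses only the region
resolved in most deposited structures; restraints extend further toward the
termini (completed by `graft_residues()` in ideal geometry where needed);
analysis trims one more residue at each end, where fraying is expected and
uninformative.

### Stage A: template-pair ranking

`rank_template_pairs()` takes two lists of candidate fibril models,
extracts the aligned backbone (N, CA, C) windows of one chain from each,
Kabsch-superposes them (`superpose()`, a closed-form least-squares fit via
singular value decomposition with a proper-rotation guarantee), and ranks
pairs by backbone RMSD. Candidates whose resolved residue range does not
cover the template window are filtered out rather than silently truncated,
because a shorter overlap makes RMSDs incomparable across pairs.

The premise is that a low backbone RMSD between the two folds over the
aligned core predicts a junction where the β-sheet hydrogen-bonding ladder
can continue across the species boundary with minimal strain.

## Stage B: restraints and the coarse-grained engine

### β-sheet restraints

`beta_sheet_restraints()` places one harmonic CA:CA restraint per residue
pair across every adjacent-chain interface:

* homomeric interfaces restrain residue *i* to residue *i* (in-register
  parallel stacking),
* the junction interface restrains the *aligned* pairs (34 for the worked
  case),

all with equilibrium distance `r0 = 4.8` Å and force constant
`k = 5` kcal mol⁻¹ Å⁻². For the 4+4 worked-case stack this gives
3 × 42 + 3 × 37 + 34 = 271 restraints. The energy is ½·k·(r − r0)² per
restraint; 5 kcal mol⁻¹ Å⁻² is soft enough to let sterics resolve clashes
but stiff enough that a satisfied restraint holds the pair within the
hydrogen-bonding criterion used downstream.

### Graded shape restraints

Distance restraints alone would let chains unfold while keeping their
junction register. `shape_restraints()` therefore adds intra-chain CA:CA
restraints taken from each chain's reference geometry (all pairs with
sequence separation ≥ 2 and reference distance ≤ 12 Å — a distance-matrix
representation of the fold, rotation- and translation-invariant by
construction).

Their force constants are *graded by chain* under `shape_schedule()`:
chains at the junction get the weakest bias (maximum conformational
freedom to form the new interface), chains far from it the strongest
(anchoring the homomeric stacks). Six profiles are provided, because how
quickly rigidity should grow away from the junction is a genuine modeling
choice rather than a derivable quantity:

| variant | profile |
|---|---|
| 1 | linear in chain distance from the junction |
| 2 | quadratic (convex — freedom extends further) |
| 3 | exponential approach to the maximum |
| 4 | sigmoidal step at the midpoint |
| 5 | hard step: only the outermost chains fully biased |
| 6 | uniform minimum (control: no grading) |

All profiles share the same endpoints (`k_min` at the junction chains,
`k_max = 5` at the outermost, except variant 6), so comparisons across
variants isolate the grading shape.

### The coarse-grained engine

The refinement engine is a deliberate desk-scale surrogate for a restrained
all-atom simulation. Each residue is one bead at its CA position
(`build_cg_topology()`); the potential is

* pseudo-bonds between consecutive beads, harmonic with `r0 = 3.8` Å,
  `k = 20` kcal mol⁻¹ Å⁻² (the CA–CA virtual bond length),
* soft-sphere sterics: quadratic repulsion below a 4.0 Å contact distance,
  `k_rep = 10` kcal mol⁻¹ Å⁻², between all non-bonded bead pairs,
* the β-sheet, junction and shape restraints described above.

Relaxation is steepest descent with a backtracking line search
(`minimize()`), robust for a potential that is piecewise smooth with
quadratic walls. Sampling is Langevin dynamics with the BAOAB splitting
(`langevin_run()`), `dt = 0.01` ps, friction 1 ps⁻¹ by default — BAOAB
gives accurate configurational averages at large step sizes, which matters
because the surrogate runs are short. The integrator records per-frame
kinetic temperature so thermostat behavior is checkable.
`backmap_trajectory()` re-dresses each CG frame with the full backbone by
rigidly fitting each residue's reference geometry to its bead, so the
atomistic analyses below can run on CG output.

### The refinement protocol: damped relaxation, not finite-T sampling

The shipped end-to-end protocol minimizes and then runs a short
*zero-temperature* (fully damped) Langevin relaxation rather than sampling
at 300 K. This is a consequence of the surrogate's physics, not a tuning
convenience: distance restraints leave inter-sheet *shear* almost free —
sliding one sheet by δ changes a 4.8 Å restraint distance only by about
δ²/(2·4.8), a quartic energy in δ. In an all-atom model this mode is
stiffened by side-chain packing and backbone hydrogen-bond directionality,
neither of which exists for CA beads. At any finite temperature the CG
stack therefore shears enough that individual hydrogen-bond distances
transiently exceed the 3.5 Å criterion, even though the junction is intact
by every other measure. The damped protocol reports the restrained-optimal
junction geometry, which is what the surrogate is for; finite-temperature
runs remain available (`temperature = 300`) for studying the soft modes
themselves.

## Stage C: analysis

All analyses run on a `Trajectory` of backmapped frames.

* **`hbond_occupancy()`** — percentage of frames in which a backbone
  donor–acceptor pair satisfies distance ≤ 3.5 Å *and* donor–hydrogen–
  acceptor angle ≥ 150° (amide hydrogens are placed geometrically from the
  backbone). Reported as a residue × residue matrix for a chosen interface.
* **`contact_probability()`** — fraction of frames with any heavy-atom
  pair within 4.5 Å, per residue pair.
* **`beta_content()`** — a residue counts as β if its (φ, ψ) lies in the
  β region *and* it participates in an inter-chain backbone hydrogen-bond
  ladder with any other chain. Both conditions are needed: dihedrals alone
  call frayed, detached strands β; ladders alone call distorted turns β.
* **`qt_cluster()`** — quality-threshold clustering at a 3.5 Å backbone
  RMSD cutoff: every member of a cluster is within the cutoff of the
  cluster center, so cluster populations are directly interpretable as
  conformational-state weights (unlike k-means, which has no such
  guarantee).
* **`rmsd_series()` / `compare_polymorphs()`** — drift relative to the
  first frame, and backbone RMSD between two polymorphs over a common core
  region, averaged over chain-to-chain assignments.

### Energetics surrogate

`interaction_map()` decomposes interchain energetics residue-pairwise,
averaged over frames:

* **Polar** = Coulomb (332.0636·qᵢqⱼ/(εₚ·r), εₚ = 1) plus a
  generalized-Born cross term −½(1/εₚ − 1/ε_w)·332.0636·qᵢqⱼ/f_GB with
  f_GB = √(r² + RᵢRⱼ·exp(−r²/(4RᵢRⱼ))) and ε_w = 78.5. Effective Born
  radii come from the pairwise HCT (Hawkins–Cramer–Truhlar) approximation
  (dielectric offset 0.09 Å, overlap scale 0.8) — pairwise descreening is
  the standard desk-scale compromise between speed and accuracy.
* **Nonpolar** = Lennard-Jones (geometric-mean ε, arithmetic-mean σ,
  energy capped at 100 kcal/mol to keep clashed frames finite) plus a
  surface term −γ·(buried lens area) with γ = 0.0072 kcal mol⁻¹ Å⁻² and a
  1.4 Å probe, approximating buried solvent-accessible surface by
  pairwise sphere–sphere lens overlap.

Charges, radii and LJ parameters ship as a versioned TSV in
`inst/extdata/`. The limiting behaviors are closed-form and tested: unit
charges at 3.320636 Å give 100 kcal/mol Coulomb; the LJ minimum is −ε at
2^(1/6)·σ; vanishing Born radii recover the full-screening limit.
`residue_normalized_energy()` divides a chain's summed interface energies
by its residue count, making chains of different length (Aβ 42 vs IAPP 37)
comparable.

## What the fixtures emulate — and what they don't

`make_ideal_fibril()` builds strands with constant (φ = −119°, ψ = 113°)
β dihedrals, stacked by pure 4.8 Å translation; `make_abeta_iapp_stack()`
joins an Aβ stack and an IAPP stack at the aligned register, including
IAPP's 2–7 disulfide and C-terminal amidation in the topology metadata.
One subtlety: a constant-dihedral strand's CA trace pleats with period 2,
so an *odd* register offset would mismatch pleat phases across the junction.
The generator shifts the pleat phase of the second molecule (via
`parity_offset` in the recipe) so aligned windows are exact translates and
the ideal junction is a pure-translation, 4.8 Å-register interface.

These fixtures emulate the *geometry* of parallel in-register cross-β
stacking well enough to exercise every stage of the pipeline with exact
expected values. They do **not** emulate: side chains (beyond per-residue
parameters), fibril twist, β-arch/β-solenoid folds, water, or any
sequence-dependent stability difference. Conclusions about *which* peptide
pair forms a better junction require real polymorph structures in Stage A;
the fixtures are for validating machinery and protocols, not biology.

## Limitations

* The CG engine has no attractive nonbonded term; cohesion comes entirely
  from restraints. It cannot predict whether a junction forms — only what
  the restrained-optimal junction looks like and how stiff it is.
* The GB/SASA surrogate uses pairwise approximations throughout; energies
  are comparative (chain vs chain, polymorph vs polymorph), not absolute.
* Gapless alignment assumes a single register; peptide pairs whose best
  correspondence requires gaps are out of scope.
* Backmapping is per-residue rigid fitting; it preserves the reference
  dihedrals, so β-content on backmapped CG trajectories reflects ladder
  integrity, not dihedral sampling.
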