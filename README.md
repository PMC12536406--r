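# crossbeta

Modeling heteromeric amyloid junctions in axial fibril stacking.

Amyloid fibrils of different peptides can cross-interact: a preformed fibril
of one species can template elongation by another, producing a *heteromeric
junction* — a single interface where the last chain of one molecule's
cross-β stack hydrogen-bonds to the first chain of the other's. `crossbeta`
provides a desk-scale toolchain for building and analyzing structural models
of such junctions, with the amyloid-β (1–42) / islet amyloid polypeptide
(IAPP) junction as the worked case.

The package covers three stages:

* **Template selection** — gapless residue alignment between the two
  peptides' fibril-core regions and ranking of candidate fibril structure
  pairs by backbone (N, CA, C) RMSD after Kabsch superposition, with
  resolved-range filters (`gapless_align`, `superpose`,
  `rank_template_pairs`, `graft_residues` for completing unresolved
  termini).
* **Biased model refinement** — β-sheet-like harmonic CA:CA restraints
  across every adjacent-chain interface (the junction interface uses the
  alignment's residue pairing), plus intra-chain shape-similarity restraints
  whose force constants are graded by each chain's distance from the
  junction under six selectable schedules (`beta_sheet_restraints`,
  `shape_schedule`, `shape_restraints`). A coarse-grained (one CA bead per
  residue) engine relaxes and samples the restrained model: steepest-descent
  minimization with backtracking line search and a BAOAB Langevin integrator
  (`build_cg_topology`, `minimize`, `langevin_run`, `backmap_trajectory`).
* **Trajectory analysis and energetics** — hydrogen-bond occupancy maps,
  heavy-atom contact probability maps, β-sheet content, quality-threshold
  clustering, RMSD series and polymorph comparison (`hbond_occupancy`,
  `contact_probability`, `beta_content`, `qt_cluster`, `rmsd_series`,
  `compare_polymorphs`), and a generalized-Born style residue-pairwise
  decomposition of polar and nonpolar interchain energies with pairwise
  HCT Born radii and a buried-surface nonpolar term (`interaction_map`,
  `residue_normalized_energy`, `chain_energy_summary`).

The coarse-grained engine and the GB energetics are deliberately *surrogates*:
they reproduce the workflow's structure (restrained refinement, occupancy
analysis, per-chain energy comparison) at desk scale, not the numbers of an
all-atom implicit-solvent simulation. See the vignette
(`vignettes/junction-modeling.Rmd`) for the model, its assumptions and its
limits.

## Worked example

Every object in the pipeline can be generated deterministically — no
downloads required. `make_abeta_iapp_stack()` builds an idealized 4+4
heteromeric stack (chains A–D amyloid-β, E–H IAPP, junction between D and E,
4.8 Å inter-strand rise, junction residues aligned 9–42 ↔ 4–37):

```r
library(crossbeta)

stk <- make_abeta_iapp_stack(n_chains = 4)

al    <- gapless_align(region_spec("restraint")$ABETA42,
                       region_spec("restraint")$IAPP)
beta  <- beta_sheet_restraints(stk, al)      # 34 junction + 237 homomeric
sched <- shape_schedule(2, stk)              # quadratic decay toward junction
rset  <- restraint_set(beta, shape_restraints(stk, sched, stk), sched)

sys  <- build_cg_topology(stk)               # 316 beads, 308 pseudo-bonds
mn   <- minimize(sys, sys$coords, rset)
traj <- backmap_trajectory(
  langevin_run(sys, mn$coords, rset, n_steps = 500, temperature = 0,
               seed = 1, stride = 50),
  stk)

occ <- hbond_occupancy(traj, stk, c("D", "E"))
bc  <- beta_content(traj, stk, c("D", "E"))
bc$interface
#> [1] 1

maps <- interaction_map(traj, stk, c("D", "E"), stride = 5)
range(maps$polar)    # kcal/mol, residue-pairwise
```

A command-line wrapper covering the same pipeline is installed as
`exec/crossbeta` (subcommands `make-fixtures`, `select-templates`,
`make-restraints`, `run-biased`, `analyze`).

## Reproduction

`scripts/acceptance.R` runs the full pipeline against the **installed**
package and writes its principal quantities as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The report includes the restraint counts (34 junction / 271 β-sheet-like
total for the 4+4 stack), the post-minimization junction register deviation,
interior junction hydrogen-bond occupancies, interface β content, QT cluster
populations and residue-normalized per-chain polar/nonpolar energies. It
completes in well under a minute on one CPU.

## Layout

```
R/               chain/model types, IO, alignment, restraints, CG engine,
                 analysis, energetics, fixtures, CLI
inst/extdata/    GB/LJ/charge parameter table (TSV, versioned data)
inst/exec/       crossbeta CLI wrapper
tests/testthat/  unit, property and acceptance tests
scripts/         acceptance.R reproduction script
vignettes/       methods vignette (source)
```
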