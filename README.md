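# dimerbind

Time-resolved MM-PBSA decomposition of the binding energy of a two-chain
peptide (dimer) along a molecular-dynamics trajectory, with the structural
analyses that usually accompany it.

Dimerization of amyloidogenic peptides is an end-state free-energy problem:
two chains associate, and the question is which interactions — gas-phase
molecular mechanics or solvation — drive each phase of the encounter.
`dimerbind` computes, for every trajectory frame, the full MM-PBSA
bookkeeping

```
dG_bind = <G_C> - <G_A> - <G_B>          (species form)
G       = E_MM + G_sol - T S
E_MM    = E_int + E_ele + E_vdw          (Amber conventions)
dG_bind = <dE_MM> + <dG_sol>             (component form)
```

where `G_sol` is the continuum-solvent energy (polar reaction field plus a
SASA-linear cavity term) and `S` the Schlitter quasi-harmonic configurational
entropy.  Under the single-trajectory protocol (monomer coordinates excised
from complex frames) every bonded term cancels in the difference, so
`dE_int == 0` identically and the two forms agree frame by frame.

What the package provides:

* **Energies.** Bonded / Coulomb / Lennard-Jones terms with Amber 1-2/1-3
  exclusions and 1-4 scaling; a finite-difference linear Poisson-Boltzmann
  solver (harmonically smoothed dielectric boundary, SOR relaxation in
  compiled code) as the polar reference engine and a generalized Born
  (Still + HCT descreening) engine for per-frame throughput; Shrake-Rupley
  SASA with a deterministic golden-spiral point set.
* **Per-frame decomposition.** An `n_frames x 18` energy matrix (five
  components for complex, monomer A and monomer B, plus `dE_bind`, `dE_MM`,
  `dE_sol`), trajectory summaries in the species and component forms, and
  Schlitter entropies with the `-T dS` correction.
* **Time-series analysis.** Mean-centring, moving-average smoothing, and
  stage segmentation: a stage boundary is a local minimum of smoothed
  `dE_MM` coinciding with a local maximum of smoothed `dE_sol`.
* **Structure.** Hydrogen-bond detection / presence matrix / density /
  occupancy tables, Kabsch RMSD dissimilarity matrices per monomer,
  side-chain contact maps (6.5 A centre cutoff), and the ten-class dimer
  conformation taxonomy (NN/NC/CC x parallel/antiparallel, nested and
  antinested variants).
* **Replica selection.** The most representative trajectory of a
  multi-temperature set: lowest mean inter-chain interaction energy
  (electrostatic + van der Waals + solvation change) over the final window.
* **Synthetic systems.** A generator of toy two-chain systems and staged
  trajectories with planted stage boundaries, hydrogen-bond schedules and
  replica sets, so the whole pipeline is testable without external data.

## Worked example

```r
library(dimerbind)

sys  <- build_toy_dimer(5, seed = 1)                 # two chains x 5 residues
plan <- stage_plan(n_frames = 600, boundaries = c(90, 215, 370, 520), seed = 1)
traj <- generate_staged_trajectory(sys, plan)

fit <- mmpbsa(traj, sys$forcefield, solvation_config(engine = "gb"),
              temperature = 305, smoothing_window = 51)
fit
```

```
MMPBSA decomposition: 600 frames, 305 K

Binding free energy decomposition over 600 frames at 305 K (kcal/mol):
 quantity        value
  dG_bind   -2.4 (2.8)
      G_C 489.3 (93.9)
      G_A 248.2 (65.8)
      G_B 243.4 (67.9)
    dE_MM -52.7 (20.7)
   dG_sol  50.3 (18.1)

-T dS correction: -2.804 kcal/mol

Stage boundaries at frames: 99, 210, 377, 508
```

Read it as follows.  The mean binding energy is favourable
(`dG_bind = -2.4 kcal/mol`; parentheses are population standard deviations),
and it is the residual of two large opposing contributions: the
molecular-mechanics change `dE_MM = -52.7` (chains attract in the gas phase)
against the desolvation penalty `dG_sol = +50.3` (burying charged side
chains costs reaction-field energy).  The two identities
`dG_bind = G_C - G_A - G_B = dE_MM + dG_sol` hold to machine precision on
every frame.  The entropy correction is small relative to the enthalpic
terms, as expected for two identical chains.  The four stage boundaries
recovered from the smoothed, mean-centred series (frames 99, 210, 377, 508)
sit within half a smoothing window of the four closest-approach events the
generator planted (frames 90, 215, 370, 520): each boundary is a frame where
`dE_MM` is at a local minimum while `dE_sol` peaks — the anti-correlated
signature the segmentation looks for.

`plot(fit)` overlays the smoothed `dE_bind`, `dE_MM`, `dE_sol` traces with
the boundaries; `run_pipeline()` executes the whole analysis from files on
disk and writes every artifact (energy matrix, H-bond matrices, RMSD
matrices, stage report, contact map, classification, manifest) into an
output directory.  A thin command-line wrapper lives in
`inst/cli/dimerbind.R` (`synth` and `run` subcommands).

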