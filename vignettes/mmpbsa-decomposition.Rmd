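---
title: "Time-resolved MM-PBSA decomposition of dimer binding energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved MM-PBSA decomposition of dimer binding energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerbind)
```

## The model

`dimerbind` follows the association of two peptide chains (monomers A and
B forming complex C) through an end-state decomposition evaluated on every
frame of a trajectory:

$$\Delta G_{bind} = \langle G_C \rangle - \langle G_A \rangle - \langle G_B \rangle,
\qquad G = E_{MM} + G_{sol} - T S,$$

$$E_{MM} = E_{int} + E_{ele} + E_{vdw}, \qquad
G_{sol} = \Delta G_{pol} + \gamma \, \mathrm{SASA} + \beta .$$

The gas-phase terms use Amber functional forms: harmonic bonds and angles
without the 1/2 factor, cosine dihedrals $\tfrac{V_n}{2}(1+\cos(n\phi-\gamma))$,
Coulomb with $k_e = 332.0636$ kcal Å mol$^{-1}$ e$^{-2}$, and 12-6
Lennard-Jones in $r_{min}/\varepsilon$ form with Lorentz–Berthelot
combining.  Pairs one or two bonds apart are excluded; 1-4 pairs are
divided by `scee = 1.2` (electrostatics) and `scnb = 2.0` (LJ).  No
distance cutoff is applied: cutoffs belong to the dynamics engine, not to
end-state post-processing.

**Single-trajectory protocol.**  Monomer energies are computed on
coordinates excised from the complex frame.  Every bonded term then
appears identically in $E_{int}(C)$ and in $E_{int}(A)+E_{int}(B)$, so
$\Delta E_{int} \equiv 0$ and the per-frame identities
$\Delta E_{bind} = E_C - E_A - E_B = \Delta E_{MM} + \Delta E_{sol}$ hold
to machine precision.  Both identities are asserted as tests, and the
trajectory summary reports means with *population* (divide-by-$n$)
standard deviations, since the frames are treated as the complete sample
being described, not a draw from a larger one.

The analysis temperature defaults to 305 K, the temperature at which the
entropic terms of a dimerization study of this kind are usually quoted;
every function takes it as an argument.

## Solvation engines

Two polar engines stand behind one interface, `solvation_config(engine=)`:

* **`pb` (reference).**  Finite-difference linear Poisson–Boltzmann on a
  regular grid: trilinear charge spreading, screened-Coulomb Dirichlet
  boundary values, red–black successive over-relaxation in compiled code,
  and the reaction-field energy as the difference of a solvated and a
  uniform-dielectric solve *on the same grid*, which cancels the grid
  self-energy exactly.  The dielectric boundary is the union of
  probe-inflated atom spheres; faces crossing the boundary receive a
  harmonically averaged dielectric proportional to the inside fraction of
  the face segment.  This smoothing matters: with a binary dielectric map
  the energy of a small ion pair moves by more than 1% under sub-lattice
  translations, with the smoothed map by about 0.3%, and the Born-ion
  error at 0.25 Å spacing drops from about 1.5% to 0.2%.  Convergence is
  declared when the largest potential update falls below `pb_tol`
  (default $10^{-4}$ kcal mol$^{-1}$ e$^{-1}$); non-convergence within
  `pb_maxiter` sweeps is an error, never a silent result.
* **`gb` (default for trajectories).**  Still's pairwise formula with
  Hawkins–Cramer–Truhlar effective radii from pairwise descreening of the
  intrinsic radii.  A neighbour-radius scale `gb_descreen = 0.8`
  compensates the overlap double-counting of the pairwise integral, as
  descreening schemes conventionally do; a single isolated atom reduces
  exactly to the Born formula.  GB is the engine used for per-frame energy
  matrices because a PB solve per frame and species is three grid solves
  per row; PB remains the oracle the GB path is cross-checked against.

The nonpolar term uses the classic parameterization
$\gamma = 0.00542$ kcal mol$^{-1}$ Å$^{-2}$, $\beta = 0.92$ kcal mol$^{-1}$,
probe radius 1.4 Å, with Shrake–Rupley areas sampled on a deterministic
golden-spiral point set (960 points per atom by default, about 1%
accuracy on sphere areas), so SASA is bit-reproducible.  Dielectrics
default to $\varepsilon_{in}=1$, $\varepsilon_{out}=80$, zero ionic
strength; all are configurable.

## Entropy

Schlitter's quasi-harmonic upper bound is evaluated from the
mass-weighted Cartesian covariance of the selection after iterative
superposition onto the mean structure (two Kabsch passes), using
$S = \tfrac{k_B}{2} \ln\det\!\big(I + \tfrac{k_B T e^2}{\hbar^2}
M^{1/2} C M^{1/2}\big)$ with the population covariance.  When fewer than
$3n+1$ frames are available the covariance cannot be full rank; the
implementation warns and uses the pseudo-determinant over positive
eigenvalues (zero modes contribute $\ln 1 = 0$).  The binding correction
is $(-T\Delta S) = (-TS_C) - (-TS_A) - (-TS_B)$.

## Stage segmentation

Energy series are first mean-centred (`normalize_series`) and smoothed
with a centred moving average whose edge windows shrink so the output
keeps the input length.  The default window of 101 frames is about 0.4 ns
at 4 ps sampling — wide enough to suppress frame-to-frame noise, narrow
enough to keep nanosecond-scale features.  A stage boundary is a local
minimum of smoothed $\Delta E_{MM}$ lying within `match_tol` frames
(default half a window) of a local maximum of smoothed $\Delta E_{sol}$:
the opposing-extrema signature of a closest-approach event, where
gas-phase attraction peaks exactly as the desolvation penalty does.
Extrema are defined over a $\pm$`window` neighbourhood with the earliest
frame winning ties, and must protrude from that neighbourhood by at least
`prominence` — by default half the standard deviation of the series.
Without a prominence floor, smoothed noise in featureless stretches
produces shallow chance extrema that pair up across the two series and
create spurious boundaries; half an SD is far above the residual noise
ripple yet far below any genuine energetic event, and the recovery rate
on planted four-boundary series goes from roughly 80% to 100% of seeded
runs when it is applied.  Monotone series yield no boundaries; series
shorter than two windows are an error.

## Replica selection

Among trajectories run at different temperatures, the most representative
one is taken to be the replica whose mean inter-chain interaction energy
($\Delta E_{ele} + \Delta E_{vdw} + \Delta E_{sol}$, computed from the
energy matrix columns) over the final tail window is the most favourable.
"Maximizing the interaction" is read as *most negative*; a literal
maximum mode exists for sensitivity checks (`mode = "maximum"`).  Ties go
to the lowest replica index.

## Structural analyses

**Hydrogen bonds.**  Geometric criterion: donor–acceptor distance
$\le 3.5$ Å and donor–H–acceptor angle $\ge 120^\circ$ (ptraj-style
defaults; both configurable), donors are N/O with a covalently bound H,
acceptors are N/O.  Donor–acceptor pairs within three covalent bonds are
skipped, the standard guard against counting covalent neighbours — e.g.
the backbone N of residue $i{+}1$ and the carbonyl O of residue $i$ sit
2.2 Å apart through two bonds and are not a hydrogen bond.  The presence
matrix enumerates every triple observed in at least one frame, with no
occupancy threshold; occupancy is the percentage of frames a bond is
present, sorted descending with ties broken by column order.

**RMSD.**  Pairwise dissimilarity matrices use Kabsch least-squares
superposition (via bio3d); the matrix is computed per monomer selection,
since the two chains' conformational histories are analysed separately.

**Contact maps.**  Two residues are in contact when their side-chain
geometric centres are within 6.5 Å (CA fallback for residues without
side-chain atoms).  Trajectory maps hold the fraction of frames in
contact, binarizable with a threshold.

**Conformation taxonomy.**  The ten-class dimer classifier rests on
β-hairpin detection on the CA trace: a turn is a local direction reversal
of at least `turn_angle` (100°) between the incoming and outgoing
directions over `turn_window` (2) residues, flanked by two strands of at
least `min_flank` (2) residues whose end-to-end length is at least
`ext_frac` (0.75) of their contour length.  Two hairpins give NN/NC/CC by
which terminus each monomer's interface strand (most inter-chain contacts)
contains, crossed with parallel/antiparallel by the sign of the dot
product of the interface strands' end-to-end vectors.  One hairpin with
the other chain wrapped around it (hairpin centroid within half the outer
chain's extent of its centroid) gives nested/antinested by which side of
the hairpin opening the outer termini lie, crossed with the same
orientation test.  Everything else is `unclassified` — the classifier is
total and deterministic.  These thresholds are deliberate
reconstructions of a qualitative geometric description; they are all
exposed in `classifier_control()` and validated on constructed ideal
geometries, not on borderline cases.

## The synthetic generator

`build_toy_dimer()` makes two identical chains of six-atom residues
(backbone N, H, CA, C, O plus one side-chain pseudo-atom SC carrying the
residue charge: basic +1, acidic −1, polar/hydrophobic 0).  Each chain
carries a basic residue at its start and an acidic one at its end so
salt-bridge-like contacts can form; remaining residue types are drawn
reproducibly from the polar/hydrophobic pool.  The SC pseudo-atom stands
for an entire side-chain group and is parameterized accordingly (larger
LJ sphere and well depth, intrinsic radius 2.3 Å): with bare-ion radii
the desolvation penalty of the ±1 sites overwhelms every attraction and
the dimer has no bound optimum at all, which would contradict the staged
anatomy the generator must plant.  Equilibrium bond lengths and angles
are read off the built geometry, so the rigid template is the bonded
minimum and $E_{int}$ fluctuates only with the coordinate noise.

`generate_staged_trajectory()` moves chain B rigidly along a separation
profile with plateaus between boundaries and dips to `boundary_sep`
(4.8 Å) at each planted boundary, adds Gaussian coordinate noise
(0.08 Å), and realizes hydrogen-bond schedules by snapping the scheduled
acceptor onto the donor's N–H axis in exactly the frames dictated by a
deterministic Bresenham-style occupancy pattern — so planted occupancies
are recovered *exactly*, not statistically.  Default boundaries sit at
fractions 2.8/19, 6.8/19, 11.7/19 and 18.2/19 of the frame range, the
stage anatomy of a 19 ns dimerization window.  Because closest approach
simultaneously deepens the gas-phase attraction and raises the
desolvation penalty, the generated $\Delta E_{MM}$ and $\Delta E_{sol}$
series are anti-correlated (correlation below −0.9 in tests) with
opposing extrema at the boundaries — precisely the structure the
segmentation consumes.  `generate_replica_set()` gives each temperature a
constant separation growing with distance from the designated best
temperature (305 K) and noise scaling with $\sqrt{T/305}$, planting a
known answer for the selection criterion.

What the generator does *not* emulate: real dynamics (no thermostat, no
inertia, no water), secondary-structure propensities, side-chain
rotamers, or conformational exchange between stages.  Passing tests
therefore demonstrate that the *analysis* recovers planted truth under
realistic statistical structure — not that the toy force field reproduces
any particular peptide's energetics.

## Numerical choices and degenerate inputs

* Frame sampling uses a half-open window (last frame included, window
  start excluded), so a 19 ns window at 4 ps yields exactly 4750 frames;
  the frame count is `floor(window/interval)` for all valid pairs.
* The PB grid anchors to the solute bounding box plus `grid_padding`
  (12 Å default); an atom within one spacing of the boundary is an error.
  SOR uses the Chebyshev-style relaxation factor
  $\omega = 2/(1+\sin(\pi/n_{max}))$.
* Overlapping atoms (pair distance < 0.1 Å) make Coulomb/LJ error rather
  than return astronomically large numbers; the generator retries noisy
  frames that place atoms closer than 0.5 Å and errors after 20 attempts.
* Zero-noise static plans produce bit-identical frames, constant energy
  rows, zero RMSD matrices and zero Schlitter entropy; all are tested as
  degenerate cases.
* Fixed seeds make every generator output bit-identical; the pipeline
  writes byte-identical CSVs when rerun with the same configuration.

## Problem sizes

The test suite and the reproduction script run on deliberately small
instances chosen to exercise every code path at interactive speeds:
4–8 residues per chain (48–96 atoms), trajectories of 10–1200 frames for
unit and property tests, a single full 4750-frame decomposition in the
reproduction script, PB oracles on single ions and ion pairs at
0.5–0.125 Å spacings, and 26-replica sets of 12 frames each.  The
quadratic RMSD dissimilarity matrix is computed on trajectories of tens
of frames in tests; for production-length trajectories it is the one
artifact worth disabling (`rmsd = FALSE`) unless needed.

## Known limitations

* The dielectric region is the probe-inflated van der Waals union, not a
  molecular (reentrant) surface; for tight crevices this slightly
  overestimates the solvent region.  The bias is documented, consistent
  between engines, and irrelevant to the convex toy geometries.
* GB/HCT with a single descreening scale is a deliberately simple variant;
  it is cross-checked against PB on Born ions and asymptotic pairs, not
  against any particular production GB flavour.
* Only zero ionic strength is supported (the boundary condition is plain
  screened Coulomb).
* The hairpin classifier encodes one reasonable reading of a qualitative
  taxonomy; borderline geometries land in `unclassified` rather than being
  forced into a class.
* Multi-model PDB is the only trajectory format; binary trajectory
  formats are out of scope.
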