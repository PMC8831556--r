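---
title: "Solvation-shell-resolved liquid structure: models and methods"
author: "solvshell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solvation-shell-resolved liquid structure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solvshell)
```

## The problem this package addresses

Whether dissolved salt restructures water the way applied pressure does is
an old question in solution chemistry, with direct bearing on Hofmeister
phenomena.  Neutron diffraction sees only a composite structure factor,
which mixes solvent-solvent, ion-solvent and ion-ion correlations; a
pressure-like signature in that composite does not by itself reveal *where*
in the liquid the perturbation lives.  Simulation can answer the question
by decomposition: assign every water to an ionic first solvation shell
(FSS) or to the free water (FW) beyond all shells, recompute distributions
and structure factors over each population separately, and compare the FW
structure with the neat solvent.  `solvshell` implements that full
decomposition pipeline for species-labelled periodic trajectories, along
with the synthetic systems needed to validate every stage against analytic
geometry.

## Real-space estimators

**Radial distribution functions.** `compute_rdf()` histograms
minimum-image pair distances and divides each bin by the uncorrelated
expectation `n_alpha * 4 pi r^2 dr * rho_beta`, with the self term removed
for like pairs (`rho_beta = (N - 1)/V`), so an ideal gas gives exactly
`g = 1` in expectation.  Bins are centred on multiples of the bin width:
an exact lattice distance then falls on a bin centre, and reported peak
positions are multiples of the resolution.  The default bin width is
0.02 A and the default range is half the smallest cell edge, the largest
radius at which minimum-image shells are complete spheres.

**Angular distribution functions.** `compute_adf()` accumulates, for every
central oxygen, the angle subtended by each unordered pair of its
neighbours within a cutoff (by convention the first minimum of the
relevant g_OO).  The histogram is a plain angle density normalised to unit
integral over (0, 180]; no sin-theta Jacobian is applied, so a user who
wants a solid-angle density can multiply it back.  For subset ADFs the
default demands that the central oxygen *and* both neighbours belong to
the subset; `neighbour_scope = "all"` relaxes the neighbours, and the
choice is recorded in the result.

**Peaks and minima.** Shell radii feed back into every subset analysis, so
the finders are deliberately conservative: curves are smoothed with a
centred 3-bin moving average and a local maximum must clear a prominence
threshold (0.02 in g units by default) before it counts as structure.
Ties at a first minimum resolve toward smaller r; a flat-topped smoothed
maximum is reported at its plateau midpoint, which keeps an isolated
lattice spike (a 3-bin plateau after smoothing) centred on its true bin.
`determine_shell_radii()` works on far noisier curves than the O-O RDF
(each frame holds few ions), so it uses coarser 0.05 A bins, an extra
5-bin pre-smoothing, a prominence of 0.1 and ignores the physically empty
region below 1.5 A.  These four values are arguments, and the radii are
always logged together with the RDFs they came from.

## Reciprocal space

Partial structure factors follow the Faber-Ziman convention (S tends to 1
at large Q).  Two independent routes are provided:

* `rdf_to_structure_factor()` evaluates
  `S(Q) = 1 + 4 pi rho Int r^2 (g - 1) sinc(Qr) W(r) dr` by midpoint
  quadrature on the RDF bins, with an optional Lorch window `W`.  The
  density is by convention the total number density of the scattering
  species; it is an explicit argument.
* `debye_structure_factor()` sums `sinc(Q r_ij)` over minimum-image pairs
  within a spherical cutoff (half the cell edge) and subtracts the analytic
  uniform-background term of that cutoff,
  `4 pi rho (sin(Q Rc) - Q Rc cos(Q Rc)) / Q^3`.  Without the subtraction
  the sharp sampling-volume boundary of a periodic box injects an
  oscillation of order `rho L / Q^2` that would dwarf the liquid signal at
  small Q; with it the estimator is exact for an ideal gas at every Q.

Both routes are truncation-limited below roughly `3 * 2 pi / L`; their
mutual agreement above that limit is one of the package's standing checks.
Composite (neutron-weighted) structure factors use
`w_ab = (2 - delta_ab) c_a c_b b_a b_b / (sum c b)^2`, which sums to 1
over unordered pairs; scattering lengths are user input because they
depend on isotopic composition.  Structure factors are never vertically
shifted.

## Solvation shells and the excluded-volume correction

An oxygen belongs to the FSS of an ion when its minimum-image distance is
at most the first minimum of that species' O-ion RDF; oxygens claimed by
no ion are free water.  Claims may overlap in concentrated systems:
per-ion statistics count an oxygen in every claiming shell, while the
global FW/FSS partition deduplicates, so FW plus the union of shells is
always an exhaustive partition.  Assignment is instantaneous per frame
(static structure, no residence-time smoothing), and radii are determined
once from the whole trajectory.

Removing the shells leaves the remaining waters in a cavity-riddled
region, and their raw pair histogram is not comparable to a homogeneous
liquid's RDF.  `corrected_subset_rdf()` renormalises it by a Monte-Carlo
estimate of the geometry factor

> `F(r)` = probability that a point at distance r in a random direction
> from a uniformly random retained point is itself retained,

which is exactly the ratio of the retained-region ideal pair-distance
density to the free-box one.  The corrected curve uses the subset density
in the *retained* volume, so for uniform points in any cavity geometry it
is 1 at every r, and with no cavities the analytic shortcut makes the
reduction to the standard RDF exact.  The `g_uncorrected` field carries
the same histogram without `F(r)`; the gap between the two curves *is* the
correction.  When cavities swallow the box the correction stops meaning
anything; the computation refuses below a configurable retained-volume
fraction (default 30%), reporting the computed fraction — concentrated
1:10-like systems land in this regime.

`virtual_sq()` chains the stages — radii, assignment, cavities, corrected
subset RDF, Fourier transform — for the subsets `all`, `FW`, and
`FW + FSS(one species)`, recording every derived quantity in its output.

## Hydrogen bonds

The geometric criterion is the field standard: donor-acceptor O-O within
3.5 A and H-O(donor)...O(acceptor) within 30 degrees; water-anion bonds
use an H...X distance cutoff (by convention the first minimum of the
H-anion RDF) under the same angular condition.  Each H donates at most one
bond (smallest-angle candidate wins), so a water donates at most two.  All
thresholds are arguments and are echoed into every output.  A shell water
is *in a hydrogen-bond chain* when it is bonded to another water of the
same ion's shell and either pair member is bonded to a third, distinct
water; whether the third water may sit outside the shell is a flag
(default: it may).  Chain statistics quantify how much water-like
structure survives inside a shell — flexible anion shells show chains,
rigid cation shells barely do.

## The synthetic systems and what they do (not) show

All validation data are generated in-repo:

* **Ideal gas** — the null model; every estimator must return its exact
  uncorrelated limit.
* **Diamond-cubic oxygen network** (`make_diamond_lattice()`) — the
  analytic tetrahedral reference: nearest-neighbour distance exact by
  construction, second shell at `sqrt(8/3)` times it (4.51 A for 2.76 A),
  bond angle `arccos(-1/3) = 109.47` degrees.  With 2.76 A spacing this
  reproduces the canonical 4.5 A / 109.5 degree signatures of water's
  network.  `decorate_hydrogens()` adds two H per O, aligned with network
  bonds where a network exists, so hydrogen-bond criteria are satisfiable
  by construction.
* **Soft-sphere toy electrolyte** (`sample_toy_electrolyte()`) —
  Metropolis Monte Carlo of purely repulsive spheres, pair energy
  `(sigma_ij / r)^12` with additive diameters.  The standard conditions
  (`toy_electrolyte_system()`) are 240 solvent spheres of 2.8 A at packing
  fraction 0.366 (a water-like oxygen density of 0.032 per cubic
  angstrom) with 8 cation-anion pairs, a 1:30 salt:water mole ratio;
  cation and anion diameters are 2.04 and 3.62 A, twice the NaCl ionic
  radii of 1.02 and 1.81 A, so the cation shell is tight and the anion
  shell wide.  The temperature-like parameter is 1; trial moves of
  0.35 A give ~55% acceptance.  The first half of every run is discarded
  as equilibration and frames are sampled evenly from the rest (the
  validation suite uses 2400 sweeps and 128 frames; per-frame energies are
  retained in the metadata for monitoring).
* **Constant-pressure proxy.**  Mixture cells are sized to hold the
  *packing fraction* equal to the pure solvent's rather than reusing the
  pure-solvent volume.  Dissolving ions at fixed volume compresses the
  solvent — a genuine pressure increase that the free waters share, which
  would conflate the two effects the decomposition is meant to separate.
  Solutions prepared at fixed packing mimic mixtures equilibrated at a
  common pressure, which is the regime the analysis targets.

The toy model has no electrostatics, no orientational forces and no
hydrogen-bond energetics: passing tests show that the *estimators* are
correct (geometry, normalisations, corrections, orderings), not that
soft spheres reproduce water.  Quantities that hinge on real water physics
— specific shell distances, ADF peak angles of hydrated ions, bonded
fractions — are validated on constructed geometries with known answers
instead.

## Numerical choices and edge cases

* Q grid 0.3-15 inverse angstroms in 0.05 steps; r bins 0.02 A (0.04-0.05
  for subset curves, where per-bin statistics are scarcer); ADF bins
  0.5 degrees.
* The excluded-volume normalisation uses 2e5 Monte-Carlo start points per
  frame by default (3e4 in the validation suite, where the per-bin noise
  of ~0.3% sits well below histogram noise); two seeds agree within
  binomial error, and the no-cavity case bypasses sampling entirely.
* Structure-factor comparisons (free water vs pure solvent vs full
  solution) are made over `Q >= 3 * 2 pi / L`.  Below that the transform
  of a half-box-truncated g(r) is dominated by termination artifacts: a
  tail offset of 0.3% — inside the sampling noise of a 128-frame subset
  curve — moves S(0.3) by about 0.2 while leaving the valid region
  untouched.
* Degenerate inputs fail loudly: empty trajectories, inconsistent
  compositions, non-orthorhombic lattices, r_max beyond half the cell,
  orphan hydrogens, subsets that empty a frame, monotone curves with no
  first minimum, and cavity sets that leave less than 1% of the box.
* `run_pipeline()` seeds every stochastic stage from the single config
  seed; rerunning a config reproduces the report byte-for-byte.

## Known limitations

Orthorhombic cells only (minimum image stays exact and cheap); no
velocities, forces or dynamic observables; shell membership is defined on
oxygen positions only; the excluded-volume correction assumes the subset
is statistically uniform within the retained region, which degrades
gracefully but noticeably as cavities crowd the box; and the toy
electrolyte's purely repulsive shells are broader and shallower than real
hydration shells, so its first-minimum radii carry a few tenths of an
angstrom of run-to-run wander that real O-ion RDFs would not show.
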