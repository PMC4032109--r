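---
title: "Quantifying active-site preorganization from MD ensembles with mdsite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying active-site preorganization from MD ensembles with mdsite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdsite)
```

## The scientific question

Metal-dependent nucleases such as ribonuclease H carry a dense cluster of
carboxylate sidechains (the conserved DED(D) motif) that must coordinate a
divalent cation, typically Mg²⁺, for catalysis.  A long-standing question
for such active sites is whether the apo enzyme is *conformationally
preorganized* — whether the catalytic residues are already rigid and
correctly arranged before the ion arrives — or whether ion binding pays an
entropic cost to order a floppy site.  Molecular dynamics (MD) trajectory
ensembles can address this directly, through three complementary readouts
that this package implements:

1. **Sidechain generalized order parameters (S²)** of the
   carboxyl/carboxamide-bearing bonds of Asp, Glu, Asn and Gln (DENQ)
   residues, measuring ps–ns orientational rigidity;
2. **Hydrogen-bond occupancies** of the inter-sidechain network around the
   active site, measuring how persistent the supporting interactions are;
3. **Ion occupancy density maps and positional-stability metrics**,
   measuring whether a bound ion stays put and how its residence partitions
   over space.

Every analysis is paired with a seeded synthetic-trajectory generator whose
ground truth is analytic, so the estimators are verifiable end to end
without any external trajectory data.

## The order parameter

For a unit vector $\vec\mu$ along a chemical bond, the generalized order
parameter is

$$
S^2 = \frac{1}{2}\left(3\sum_{i=1}^{3}\sum_{j=1}^{3}
      \langle \mu_i \mu_j \rangle^2 - 1\right),
$$

where $i, j$ run over the Cartesian components and $\langle\cdot\rangle$ is
the arithmetic average over all frames.  This is the long-time plateau of
the second-rank angular reorientational correlation function: 1 for a fully
rigid bond, 0 for isotropic disorder.  We use the plain all-frame average —
not a windowed time-correlation fit — because the plateau value depends
only on the orientational distribution sampled, not on its kinetics.  The
estimator's algebraic range extends down to $-1/2$ for finite noisy
samples; values meaningfully below 0 indicate too few frames, not physics.

Two closed forms anchor the tests.  Diffusion in a cone of semi-angle
$\theta_0$ gives $S^2 = [\cos\theta_0(1+\cos\theta_0)/2]^2$; an
equal-population two-site jump through angle $\beta$ gives
$S^2 = 1 - 3p(1-p)\sin^2\beta$.  The test suite checks recovery across
$\theta_0 \in \{10°, 30°, 60°, 90°\}$ and the two-site case against a
brute-force evaluation of the estimator on the exact two-member ensemble.

**Bond choice.** For Asp/Asn the Cβ→Cγ bond is used; for Glu/Gln, Cγ→Cδ.
These are the symmetry axes carrying the functional group that sidechain
¹³C NMR relaxation observables report on.  `extractBondVectors()` fails
loudly if a selected residue lacks the defining atoms.

**Alignment.** S² is only meaningful after overall tumbling is removed.
`alignFrames()` superposes every frame onto a reference by a per-frame
Kabsch fit over backbone N, CA, C, O atoms (no mass weighting; reflections
excluded by sign-correcting the smallest singular vector).  The backbone
fit is the conservative standard when nothing dictates otherwise.
Alignment is idempotent, and on a tumbled rigid body it restores
coordinates to machine precision.

**Uncertainty.** `blockSEM()` splits the series into `nBlocks = 10`
contiguous equal blocks (remainder frames dropped from the end), computes
S² per block, and reports the standard deviation of the block values
divided by $\sqrt{n_\text{blocks}}$.  Block averaging absorbs the serial
correlation of trajectory frames that a naive SEM ignores; ten blocks is
the common compromise between block length and the stability of the
variance estimate.  `compareS2()` calls a per-residue difference
significant when $|\Delta S^2| > 1.96\sqrt{\text{sem}_a^2+\text{sem}_b^2}$,
deliberately without multiple-testing correction: the question asked of it
is "does *any* residue differ", and leaving the per-residue test at its
nominal level makes a verdict of *no* significant differences conservative.

## Hydrogen-bond occupancy

A donor–hydrogen–acceptor triad is bonded in a frame when the
donor–acceptor distance is **strictly less than 3.1 Å** and the angular
deviation from linearity is **strictly less than 25°**.  A literal D–H–A
*included* angle below 25° is geometrically impossible for a bonded pair
(the included angle of a good hydrogen bond is near 180°), so the package
reads the angular criterion as the deviation at the donor between the D→H
and D→A directions, which is near 0° for an ideal bond.  The alternative
reading — 180° minus the included D–H–A angle — is available as
`hbondCriteria(convention = "dha-supplement")`; for well-formed geometries
the two conventions agree closely because the hydrogen lies nearly on the
D–A axis.

A residue *pair's* occupancy is the fraction of frames in which **any**
triad of the pair is bonded (OR aggregation).  This matches how network
tables are reported for carboxylate acceptors with two equivalent oxygens:
the chemical interaction persists when the bond migrates between OD1 and
OD2.  Donors contribute one triad per explicit hydrogen (hydrogens are
detected by covalent distance < 1.25 Å; the package does not place missing
hydrogens).  Backbone donors and acceptors are excluded by default —
occupancy tables of this kind concern inter-sidechain bonds — and His
nitrogens act as acceptors only when unprotonated.  Distances and angles
are rigid-motion invariant, so no alignment is required.

## Density maps and residence time

`accumulateDensity()` bins one tracked atom per frame into cubic voxels
(default edge 0.5 Å, which resolves the ~4 Å separation between the two
crystallographic metal sites of an RNase H active site by about eight
voxels).  The grid spans the atom's bounding box padded by two voxels;
voxel intervals are half-open, and values are counts divided by frames, so
the grid mass is exactly 1.  Binning is nearest-voxel with no kernel
smoothing: "occupancy" keeps exact frame-count semantics, and any contour
threshold converts directly to a minimum total residence time,
$t_\text{res} = \text{threshold} \times \text{length}$.  For example, a
0.05% contour of an 89 ns trajectory corresponds to at least 44.5 ps
(rounded up, 45 ps) spent in each displayed voxel.  Contour comparison is
`>= threshold` so the "at least" semantics hold at the boundary.  Grids
are written as OpenDX scalar fields readable by VMD and PyMOL.

## Ion positional stability

`ionRmsd()` is $\sqrt{\langle|\vec r - \vec r_\text{ref}|^2\rangle}$ in
the aligned frame, with the frame-1 position as the default reference —
the natural choice when the question is whether an ion placed at a
crystallographic site stays there, and consistent with quoting an
initial-to-final displacement alongside.  The reference is a parameter, so
about-mean or about-crystal-site variants are one argument away
(about-mean is provably minimal, and the test suite checks that).
`endpointDisplacement()` compares the mean position of the first and last
1% of frames (minimum one frame each); window means rather than single
frames keep the estimate robust to frame-level noise while remaining
window-size agnostic for drifts slower than the window.

## Superposition and ion transplantation

`kabschFit()` implements the closed-form SVD solution for the optimal
proper rigid transform, rejecting degenerate (< 3 point or collinear)
inputs.  The unit tests hold it to three independent standards: exact
recovery of applied transforms, a brute-force oracle of 1,000 random
rotations it must beat, and agreement with an established reference
implementation.  `transplantIon()` uses the same fit to carry a
crystallographic ion position from one structure into another — the
standard modeling move when the ion-bound crystal form is disordered and
the apo form is the better scaffold.

## The synthetic generators

The generators produce trajectories whose correct analysis result is known
in closed form, in the package's standard formats:

| generator | emulates | truth |
|---|---|---|
| `genConeTrajectory()` | uniform wobble in a cone on a poly-Asp scaffold | $S^2=[\cos\theta_0(1+\cos\theta_0)/2]^2$ |
| `genTwoSiteTrajectory()` | rotamer-jump-like two-orientation exchange | $S^2=1-3p(1-p)\sin^2\beta$ |
| `genHbondTrajectory()` | telegraph hydrogen bond (2.9 Å/5° bonded, 4.5 Å unbonded) | occupancy $=p$ |
| `genConfinedIonTrajectory()` | harmonically confined ion, AR(1) kinetics | center, per-axis $\sigma$; RMSD $=\sqrt3\,\sigma$ |
| `applyGlobalTumbling()` | overall rotation + translation noise | alignment must restore the untumbled twin |

Scaffolds are chemically minimal ideal-geometry fragments, not physical
peptides; only the atoms each analysis consumes are guaranteed present.
Cone and telegraph generators draw frames i.i.d. — the plateau S² and the
occupancy depend only on the stationary distribution — while the
confined-ion generator uses a discrete Ornstein–Uhlenbeck process
(stationary Gaussian, AR(1) coefficient 0.9 per 10 ps frame) so that
time-windowed estimators see realistic serial correlation.  All generators
are bit-reproducible for a fixed seed and restore the caller's RNG state.

What the generators deliberately do **not** emulate: force-field physics,
solvent, coupled multi-residue motions, correlated rotamer kinetics, and
conformational exchange slower than the trajectory.  Passing tests
therefore certify the *estimators* — that the analyses recover known
orientational distributions, occupancies and confinement widths — not the
realism of any force field, and say nothing about sampling adequacy of a
real 100 ns trajectory.

## Numerical choices and degenerate inputs

* Coordinates and grids are in Å; times in ps internally (frame spacing is
  a required user input — no trajectory format carries it reliably), with
  ns appearing only in lengths and residence-time conversions.
* Multi-model PDB is the primary trajectory dialect; DCD is supported
  behind the same reader.  PDB coordinate precision (0.001 Å) bounds
  round-trip error; the tests confirm S² changes by < 10⁻³ across a
  write/read cycle.
* Unit-vector inputs to `computeS2()` are validated to 10⁻⁴; bond vectors
  are re-normalized per frame at extraction.
* `kabschFit()` declares inputs collinear when the second singular value
  falls below 10⁻⁸ of the first.
* Block averaging drops remainder frames from the *end*, keeping blocks
  contiguous and equal-sized.
* Half-open voxel intervals make binning deterministic at voxel
  boundaries; the grid origin is derived from the data, so grid values are
  invariant under common rigid motion of the scene.
* Result tables are written with fixed `%.6g` formatting so identical runs
  are byte-identical.

## Problem sizes used in the checks

The self-checks run at sizes chosen to keep statistical error an order of
magnitude inside each tolerance: 10⁶ frames for cone/isotropic S²
recovery (tolerance 0.01), 10⁵ for the two-site jump and ion RMSD, 10⁴
for hydrogen-bond occupancy (binomial SD ≈ 0.005 at p = 0.3) and density
centroids, and 5 × 10³ frames for the tumbling-removal comparison, whose
error is set by PDB-precision effects rather than sampling.

## Known limitations

* No time-correlation-function fitting (model-free τₑ, iRED); the S²
  reported is the plateau of the sampled distribution.
* No hydrogen placement: structures must carry explicit hydrogens for
  hydrogen-bond analysis.
* Single-atom density fields only; no solvent densities or symmetry
  averaging.
* No binding-kinetics survival analysis; residence time enters only
  through the occupancy-contour conversion.
* `readPdbStructure()` keeps the first model and altloc ''/'A' only —
  deterministic, but it silently discards minor conformers.
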