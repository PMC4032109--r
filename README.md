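# mdsite

Trajectory-ensemble analyses for asking whether an enzyme active site is
**conformationally preorganized** — rigid and correctly arranged for
cofactor binding before the cofactor arrives.  The motivating system is the
ribonuclease H family, whose conserved DED(D) carboxylate cluster binds
catalytic Mg²⁺, but every analysis is generic to any protein MD ensemble.

For structural biologists and simulators, the package computes, from
multi-model PDB (or DCD) trajectories:

* **Sidechain generalized order parameters** for Asp/Glu/Asn/Gln residues,

  S² = ½ (3 Σᵢ Σⱼ ⟨μᵢ μⱼ⟩² − 1),

  the long-time plateau of the second-rank reorientational correlation of
  the Cβ→Cγ (D/N) or Cγ→Cδ (E/Q) bond unit vector μ — 1 for a rigid
  sidechain, 0 for isotropic disorder — with block-averaged standard
  errors and a 1.96·SEM cross-condition significance comparison;
* **Hydrogen-bond occupancies** under geometric criteria (donor–acceptor
  distance < 3.1 Å, deviation from linearity < 25°), aggregated per
  residue pair over all donor-H/acceptor triads;
* **Ion occupancy density grids** (OpenDX output) with occupancy-contour →
  residence-time conversion, and **ion positional-stability metrics**
  (RMSD about a reference position, initial-to-final displacement, site
  distances);
* **Kabsch superposition** for global-motion removal and for transplanting
  crystallographic ion positions between structures;
* **Seeded synthetic-trajectory generators** (cone wobble, two-site jump,
  telegraph hydrogen bond, harmonically confined ion, global tumbling)
  whose ground truth is analytic, so every estimator is testable without
  external data.

See the methods vignette (`vignettes/mdsite-methods.Rmd`) for the models,
conventions and numerical choices.

## Worked example

Compare sidechain rigidity between two conditions (here, synthetic
ensembles wobbling in 25° vs 20° cones — stand-ins for apo vs ion-bound
trajectories), then profile a confined ion:

```r
library(mdsite)

apo   <- genConeTrajectory(25, n = 20000, nResidues = 4, seed = 11)
bound <- genConeTrajectory(20, n = 20000, nResidues = 4, seed = 12)
orderParameters(apo$trajectory)
#>   chain resNo resName  bond    s2      sem nFrames nBlocks
#> 1     A     1     ASP CB-CG 0.748 0.000735   20000      10
#> 2     A     2     ASP CB-CG 0.747 0.000900   20000      10
#> 3     A     3     ASP CB-CG 0.746 0.000943   20000      10
#> 4     A     4     ASP CB-CG 0.747 0.001205   20000      10

compareS2(orderParameters(apo$trajectory), orderParameters(bound$trajectory))
#>   chain resNo resName deltaS2 pooledSem significant
#> 1     A     1     ASP -0.0831   0.00115        TRUE
#> 2     A     2     ASP -0.0836   0.00113        TRUE
#> 3     A     3     ASP -0.0845   0.00115        TRUE
#> 4     A     4     ASP -0.0835   0.00152        TRUE
```

An S² of 0.75 is a moderately rigid sidechain; the 0.08 difference between
the conditions dwarfs its pooled standard error, so every residue is
(correctly) flagged as significantly more rigid in the tighter ensemble.

```r
g       <- genConfinedIonTrajectory(0.2, n = 20000, seed = 13)  # sigma 0.2 A
aligned <- alignFrames(g$trajectory)                 # remove global motion
grid    <- accumulateDensity(aligned, g$ion, spacing = 0.5)
contourMask(grid, 0.10)$nVoxels
#> [1] 1
occupancyToResidence(0.10, trajLength(aligned))$ps
#> [1] 20000
tr <- ionTrace(aligned, g$ion)
ionRmsd(tr); endpointDisplacement(tr)
#> [1] 0.439
#> [1] 0.175
writeDensityDX(grid, "ion-density.dx")               # view in VMD / PyMOL
```

A single voxel above 10% occupancy (each such voxel representing ≥ 20 ns
of residence in this 200 ns-equivalent trace), an RMSD of 0.44 Å about the
starting position and a 0.18 Å initial-to-final displacement are the
signature of a stably bound ion; an unstable one shows a scattered
low-occupancy cloud and RMSDs of several Å.

A command-line interface over the same functions is installed at
`inst/scripts/mdsite-cli.R` with subcommands `s2`, `hbonds`, `density`,
`ion`, `synth` and `transplant`; see `?runCli`.

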