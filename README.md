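# c2memdyn

Trajectory analysis for peripheral membrane proteins, built around the
membrane association of the SynGAP C2 domain and its missense variants.
Peripheral C2 domains dock onto lipid bilayers in recurrent orientations
("top": principal axis normal to the membrane plane; "side": axis parallel,
broader contact surface) and then diffuse laterally on the membrane. The
package provides, as tested R functions:

- **Binding-mode detection and classification** — per replica, the binding
  event (first persistent contact under a distance/persistence criterion),
  the per-residue mean minimal-distance fingerprint after binding, and
  agglomerative clustering of fingerprints across replicas with clusters
  named top/side by their median orientation angle.
- **Lateral diffusion** — mean-squared displacement of the in-plane center
  of mass, MSD(t) = ⟨|r(t) − r(0)|²⟩ (ensemble-origin or time-averaged over
  all origins), with the 2D Einstein relation D = MSD(t)/4t realized as
  slope/4 of a linear fit; per-condition summaries with log₁₀ distributions
  for box plots.
- **Lipid contact propensities** — per residue × lipid class (POPC, POPS,
  POPI), the fraction of post-binding frames in contact under a cutoff, and
  variant-vs-WT differentials.
- **Conformational statistics** — Kabsch superposition, RMSD, radius of
  gyration, RMSF, covariance PCA with basin projection and overlap, and
  covariance correlation between conditions.
- **A synthetic-data generator** — 2D Brownian trajectories with a planted
  diffusivity, a two-leaflet bilayer of pseudo-lipids with the standard
  90/17/3/3 POPC/POPS/PI(2,5)P/PI(2,4)P per-leaflet composition, scripted
  approach-and-binding trajectories with a planted mode, and Gaussian
  conformational ensembles with planted per-residue fluctuations — so every
  estimator is validated against known ground truth.

Coordinates are in Å, times in ns, diffusivities in Å²/ns. Boxes are
orthorhombic with periodic boundaries in the membrane plane.

## Worked example

Generate ten synthetic binding replicas (five planted per mode), detect the
binding events, classify the modes and estimate per-mode diffusivities:

```r
library(c2memdyn)

cfg <- pipelineConfig(
  replicas = data.frame(mode = rep(c("top", "side"), each = 5),
                        plantedD = rep(c(22, 13.4), each = 5)),
  nFrames = 300, approachFrames = 50, seed = 42)
res <- runReplicaPipeline(cfg)

res$assignment
#> ModeAssignment: 10 replicas
#>
#> side  top
#>    5    5
#>   median orientation (deg): top=1.8, side=88.4
res$diffusivitySummary
#>   condition n    meanD       sem  log10Q1 log10Median  log10Q3
#> 1       top 5 17.07177 4.6170003 1.061703    1.127129 1.197742
#> 2      side 5 13.42033 0.9077663 1.093273    1.120128 1.170855
res$events[["top_01"]]
#> BindingEvent: bound at frame 55 (cutoff 4.00 A, persistence 5.00 ns)
```

All ten replicas land in the planted cluster, the orientation medians
separate the modes cleanly (1.8° vs 88.4°), and the per-mode mean D orders
as planted (22 vs 13.4 Å²/ns) — noisily here, because five 300-frame
replicas per mode is a demonstration size; the validation suite uses 100
long trajectories per condition.

The diffusion estimator alone, against a planted truth:

```r
bm <- makeBrownian2D(D = 22, nSteps = 5000, dt = 0.1, nTraj = 20, seed = 1)
D <- vapply(estimateDiffusion(bm$unwrapped, dt = 0.1), diffusionCoefficient, 1)
sprintf("recovered D = %.1f +/- %.1f A^2/ns (planted 22)", mean(D), sd(D)/sqrt(20))
#> "recovered D = 22.3 +/- 2.2 A^2/ns (planted 22)"

parseVariant("A301T", severity = "VUS")
#> VariantRecord: A301T [VUS]
```

## Documentation

The methods vignette (`vignettes/membrane-binding-analysis.Rmd`) describes
the estimators, their assumptions, the synthetic-data model and the
numerical choices in detail; every exported function carries full help.
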