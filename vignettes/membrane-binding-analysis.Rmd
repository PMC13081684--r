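---
title: "Membrane binding modes, lateral diffusion and conformational statistics"
author: "c2memdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane binding modes, lateral diffusion and conformational statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c2memdyn)
```

# Scope and data model

`c2memdyn` analyzes trajectories of a peripheral membrane protein — the
motivating system is the SynGAP C2 domain, residues 253–413 — near a lipid
bilayer lying in the *xy* plane. The central container is the
`TrajectoryEnsemble`: a frames × atoms × 3 coordinate array in Å, per-frame
orthorhombic box lengths, strictly increasing timestamps in ns, and a
`SystemTopology` that labels every atom with its author residue number,
mass, group (protein / lipid / solvent / ion) and, for lipids, a class in
{POPC, POPS, POPI}. Author residue numbering is preserved verbatim so that
loops (370–395), termini (253–260, 405–413) and variant positions
(e.g. A301T) can be addressed directly; internal array indices are 1-based
with an explicit residue → atom-range mapping.

Both phosphoinositide species present in the simulated bilayers, PI(2,5)P
and PI(2,4)P, map to the single contact class POPI, because contact
analyses stratify by the three headgroup families only. The mapping table
(`defaultLipidClassMap()`) is user-editable at the reader boundary.

Periodic boundaries are applied in *x* and *y* via the minimum-image
convention. PBC in *z* is deliberately ignored for protein–membrane
distances: with the bilayer as the *z* reference, periodic images above and
below the slab are never the nearest physical contact in these systems.
Triclinic cells are rejected with an explicit unsupported-format error —
membrane systems here are rectangular, and the restriction keeps the PBC
arithmetic exactly testable.

# Binding-mode detection and classification

**Binding event.** A replica is bound from the first frame at which the
minimum protein–lipid distance drops below a cutoff and stays below it
continuously for at least a persistence time. The defaults — 4.0 Å and
5 ns — are standard heavy-atom contact values; the criterion itself is an
operational choice (spontaneous-binding simulations report the event but
rarely a formal criterion) and both parameters are configurable and echoed
into every output.

**Fingerprint.** For each protein residue, the per-frame minimum over all
residue-atom × lipid-atom distances, averaged over the post-binding window.
Minimal distances use *all* lipid atoms by default (not only phosphates),
with the selection configurable; the per-residue reduction makes
fingerprints comparable across replicas and variants.

**Clustering.** Replica fingerprints are clustered agglomeratively on
Euclidean distances and the tree is cut at *k* = 2 — the two recurrent
binding configurations. Average linkage is the default because it is
robust to unequal cluster sizes; ward.D2, complete and single are
available, and the full merge tree is always retained so other cuts can be
inspected. Which library default an upstream "dendrogram with default
algorithm" analysis used is not knowable, so the linkage is an explicit
configuration option rather than a fixed fact.

**Naming.** The cluster whose replicas have the smaller median post-binding
orientation angle — the angle between the membrane normal and the largest
principal axis of the protein's mass-weighted gyration tensor, folded into
[0°, 90°] — is named *top*, the other *side*. An exact orientation tie is
broken by fingerprint depth (the cluster in deeper contact becomes *side*)
with a warning. Frames whose top two gyration eigenvalues agree within a
relative gap of 10⁻⁶ have no defined principal axis; they are flagged and a
degeneracy warning is emitted rather than silently dropped.

# Lateral diffusion

The in-plane center-of-mass path is unwrapped by accumulating minimum-image
frame-to-frame displacements — exact whenever the true per-frame step is
below half the box edge, a condition that wrapped data cannot verify and
which is therefore documented rather than checked.

Two MSD estimators are provided. The *ensemble-origin* mode is the literal
definition MSD(t) = (1/N) Σⱼ |rⱼ(t) − rⱼ(0)|², averaging squared
displacements from the first frame across trajectories. The *time-averaged*
mode additionally averages over all time origins within each trajectory and
is the default: for free Brownian motion both are unbiased, but time
averaging has far lower variance at equal data. Both are validated against
a brute-force double loop over origins and lags. Non-uniform time steps are
a hard error — no silent interpolation.

In two dimensions D = MSD(t)/4t at long times, so D is fitted as slope/4 of
a least-squares line over a lag window. The default window spans 2–20% of
the trajectory duration: below ~2% the curve can be contaminated by
short-time artifacts, beyond ~20% by the growing variance and correlation
of time-averaged MSD points and by confinement plateaus. The fit is
origin-free by default (an intercept absorbs offset-like contamination; a
through-origin option exists). Negative fitted slopes are clipped to D = 0
with a warning, and log₁₀D (reported for box-plot summaries; base 10 is the
package's convention for "log-transformed") is defined only for D > 0.
Per-condition summaries report the mean and the standard error of the mean
across replicas — with a single replica the SEM is reported as absent, not
zero.

Units are fixed to Å²/ns throughout. Diffusivity tables whose units are
not printed are interpreted in these units when used as planted truths;
this is a units convention of the package, not a claim about the source of
any particular number.

# Conformational statistics

Superposition is weighted Kabsch (SVD with a determinant correction, so
reflections are never returned). RMSD and radius of gyration are
mass-weighted over the selection; RMSF and PCA reduce each residue to a
representative atom — the Cα where present, the residue bead in synthetic
systems. This per-residue reduction realizes the "rows = residues"
formulation of conformational PCA as a 3N-coordinate covariance over
representative atoms; that reading is an interpretation and is flagged as
such.

RMSF superposes all frames on their *converged mean structure*: frames are
fitted to the current mean, the mean is recomputed, and the loop repeats
until the mean moves less than 10⁻⁶ Å RMS (initialized at the first frame;
more than 100 iterations raises a convergence error rather than returning a
half-converged profile). For an isotropic Gaussian ensemble with
per-coordinate scale σ the expected RMSF is σ√3, which the tests use as a
closed-form oracle.

The PCA basis stores the converged mean, all eigenvectors and the
non-negative, descending eigenvalues; rank deficiency (fewer frames than
coordinates) is allowed with a warning, since trailing zero modes are
legitimate. Cross-condition projections always use the *reference* basis —
variants are projected onto the wild-type plane by mapping residues by
position, never onto a re-fitted basis, otherwise basin comparisons are
meaningless.

Basin overlap is the fraction of a cloud's frames inside the reference
cloud's convex hull. The hull is the default because it is parameter-free
and deterministic; a 95% kernel-density contour (`method = "kde"`) is
provided for figure parity, since the "region explored" shading in
published projections has no stated definition and both readings are
defensible. Hull membership uses a relative tolerance of 10⁻⁹ on the edge
cross-products so that a cloud always lies inside its own hull despite
floating-point noise.

Equilibrium distributions (RMSD, Rg) discard the first 25% of frames by
default. The cut is configurable; "equilibrium regime" is not given a
formal definition anywhere upstream, so the package treats it as an
explicit parameter.

Three canonical region masks are built in: the full domain, the domain
without the N-/C-terminal residues (253–260, 405–413), and additionally
without the large flexible loop (370–395) — the standard progression for
separating core stability from peripheral flexibility.

# The synthetic-data generator

The generator produces data with exactly the statistical structure the
estimators assume, so every stage is testable without molecular-dynamics
output (no trajectories are publicly deposited for the motivating system).

- **Brownian trajectories.** Increments are i.i.d. Gaussian per axis with
  variance 2·D·dt. Optional periodic wrapping or a reflecting disc
  (mutually exclusive boundary models). One root seed spawns per-trajectory
  child seeds by a fixed affine rule, so enlarging `nTraj` never reshuffles
  earlier trajectories and identical seeds give bit-identical output.
- **Bilayer fixture.** Two leaflets of single-bead "headgroup"
  pseudo-lipids on a jittered square lattice (default spacing 8 Å, leaflet
  separation 35 Å), with per-leaflet class counts 90 POPC / 17 POPS /
  3 PI(2,5)P / 3 PI(2,4)P — the standard simulated composition. Classes are
  assigned to lattice sites in seeded random order, or with the
  phosphoinositides gathered into a patch when a patch center is given
  (used to plant lipid-preference signatures).
- **Binding trajectories.** A rigid bead-per-residue body (~40 Å long)
  starts at a minimum membrane distance of 15 Å (≥ 12 Å, the unbound
  initial condition), descends with a square-root profile during the
  approach window — fast initial drop, slow final approach, so the contact
  cutoff is crossed close to the scripted binding frame — and stays bound
  at a 1.5 Å gap in the planted orientation, while its in-plane COM
  performs Brownian motion at the planted D and every bead receives
  per-frame Gaussian jitter (default 1 Å). The top-mode contact set is a
  flattened tip of the body, the side-mode set a protruding lateral band;
  the exact residue lists are fixture configuration, not biology claims.
  The membrane beads are static.
- **Gaussian ensembles.** Each frame is a reference structure plus
  isotropic Gaussian displacements with per-residue scales; no rigid-body
  motion is added, so the planted RMSF is σᵢ√3 exactly.

What the generator does *not* emulate: realistic lipid geometry or
dynamics, binding/unbinding kinetics beyond one scripted event, anomalous
or mode-switching diffusion, force-field energetics, internal protein
dynamics coupled to binding. Passing tests therefore demonstrate that the
estimators recover planted parameters under their stated assumptions —
they do not validate the estimators against the pathologies of real MD
data (membrane undulations, correlated noise, slow equilibration).

# Validation sizes and determinism

The test suite validates, among others: diffusivity recovery at the
studied conditions (100 free trajectories of 5,000 steps at dt = 0.1 ns
per condition, planted at 22, 13.4, 14 and 11.6 Å²/ns; the mean recovered
D must fall within two standard errors of the plant); 20-replica
binding-mode classification (10 top + 10 side at 1 Å jitter, required to
be recovered 20/20 with ordered orientation medians); exact agreement of
minimal distances, contact propensities and MSD curves with brute-force
all-pairs oracles on small systems; RMSF closed-form recovery within 2% at
5,000 frames; PCA eigenvalue-sum conservation to 10⁻⁸ relative; and exact
unwrap/wrap round-trips. These sizes were chosen as the smallest that make
the stochastic checks statistically decisive.

Every stochastic function takes an explicit seed and is bit-reproducible;
the pipeline echoes its full effective configuration into each output
bundle, so a result file always records how it was produced.

# Known limitations

- Orthorhombic boxes only; curved or undulating membranes and
  leaflet-resolved midplanes are out of scope.
- The binding criterion and contact cutoffs are operational defaults, not
  fitted quantities; conclusions that hinge on an absolute propensity value
  should sweep the cutoff (propensities are monotone in it by
  construction).
- Diffusion fits assume free 2D diffusion inside the fit window; confined
  or anomalous motion biases D downward (the confinement case is covered by
  tests, the anomalous case is not modeled).
- Variants enter as parsed substitution labels; no structural mutagenesis
  is performed.
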