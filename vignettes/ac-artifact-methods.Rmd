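---
title: "Simulating and correcting attenuation-map artifacts in cardiac PET/MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and correcting attenuation-map artifacts in cardiac PET/MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

PET quantification requires correcting the emission data for photon
attenuation. On integrated PET/MR systems the attenuation (mu) map is
derived from a Dixon-type MR acquisition segmented into four classes —
background/air, lung, fat and soft tissue — each assigned a fixed linear
attenuation coefficient at 511 keV (lung 0.0224 cm^-1 here; fat and soft
default to 0.0854 and 0.1000 cm^-1). These segmented maps are prone to a
well-known artifact taxonomy: susceptibility voids around sternal wires
(STN) and metallic implants (SMA), misclassification swaps between lung
and soft tissue (LSTI) or fat and soft tissue (FSTI), soft-tissue bands
above the diaphragm from breathing during the map acquisition (PMA),
truncation of the arms by the narrow MR field of view, and rigid
respiratory misalignment between the map and the emission data. For
myocardial perfusion/viability imaging these artifacts matter because a
locally wrong mu-map biases the reconstructed uptake of the nearby LV
wall, which can flip a clinical read.

`dixonac` reproduces this measurement chain end to end on synthetic
data: it generates a digital thorax phantom, injects each artifact
class, simulates attenuated emission data, reconstructs with the
artifactual and the corrected maps, and quantifies the difference with
the standard tools of the field (relative-difference maps, 42%-threshold
myocardial statistics, lung-volume test–retest, 17-segment polar maps).

## The phantom and what it does (not) emulate

The phantom is a stylized thorax, not an anthropomorphic model: an
elliptical body cylinder with a subcutaneous fat shell, arms, two lung
ellipsoids clipped at a diaphragm plane, a liver, and an LV modelled as
an annular cylinder (wall 10 mm: inner radius 22 mm, outer 32 mm) with
an apical cap, filled with a blood pool. Activity ratios default to
myocardium : blood : liver : lung : background = 8 : 2 : 4 : 0.5 : 1,
i.e. a strongly myocardium-dominant tracer distribution as in perfusion
or fasting-state FDG imaging. Everything the analysis measures —
class volumes, ring uptake, adjacency of artifacts to the wall — is
preserved at this level of abstraction. What is *not* emulated: real
anatomy textures, cardiac/respiratory motion during the emission scan,
scatter and randoms, bone (four-class maps have none), and kinetic
modelling. Passing tests therefore demonstrate the internal consistency
and the directional physics of the artifact-correction chain, not
performance on patient data.

Two geometric choices deserve explanation:

* **Axial body outline.** The body outline is non-monotone along z:
  a narrower waist below the diaphragm (scale 0.85), a full-width chest,
  and a shoulder taper (to scale 0.55) over the cranial ~22% of the
  field of view. Real torsos have exactly this structure, and it is what
  makes *rigid re-alignment identifiable*: the alignment surrogate
  maximizes the Dice overlap between the emission body-support mask and
  the mu > 0 mask, and a purely cylindrical body would make that
  objective flat (a caudally shifted cylinder nests inside the support).

* **Lung calibration.** The lung ellipsoid scale is found by bisection
  so the rasterized lung volume matches a target (2.6 L at full axial
  coverage, scaled with the axial FOV for slab grids), matching the
  cohort-scale lung volumes the lung-volume metric is meant to probe.

Organ centres receive a small seed-driven jitter (sd 1.5 mm, truncated
at 2 sd), so anatomy is a pure function of (config, seed) while
subjects differ realistically.

## Simulation and reconstruction

The emission model is 2-D parallel-beam, slice by slice: each line of
response carries the exact line integral of activity (Siddon traversal
of the piecewise-constant image; the integral is exact, not sampled)
multiplied by exp(-integral of mu), with mu in cm^-1. 210 angles over
[0, pi) give 21 interleaved subsets of 10 angles, matching the clinical
protocol of 3 OSEM iterations, 21 subsets, and a 5 mm FWHM Gaussian
post-filter (sigma = FWHM/2.3548 per axis, kernel renormalized at the
borders). The backprojector is the exact adjoint of the projector, so
plain MLEM (subsets = 1) has a monotone Poisson log-likelihood —
`poisson_loglik()` exposes the objective for verification. Attenuation
enters the system model as precomputed per-LOR factors; reconstruction
with a zero mu-map is bit-identical to the non-AC reconstruction.
Poisson counting noise is optional (`add_poisson_noise()`); the study
runner defaults to noiseless data because the artifact biases under
study are deterministic.

Numerical notes: EM updates guard against empty projections and zero
sensitivity (voxels outside the scanned field stay 0); convergence of
the mean over a thin high-contrast annulus is the slowest feature of
EM — interior wall voxels reach ~2% of truth within 20 unsubsetted
iterations while rim voxels lag, so region means over the full wall
carry a few percent of residual partial-recovery bias at clinical
iteration counts. This is a property of EM, not of the projector.

## Corrections

* **Susceptibility filling** (`fill_susceptibility`): iterative
  wavefront fill of the artifact mask. Per pass, each unassigned voxel
  with at least one assigned face-neighbour (6-connectivity) takes the
  most frequent class among assigned neighbours; ties break by the
  fixed priority soft > fat > lung > background (artifacts sit inside
  the body, where soft tissue dominates). The wavefront ordering
  propagates the surrounding tissue inward deterministically, making
  the operator idempotent and exactly restorative for artifacts
  embedded in a single class.
* **Rigid re-alignment** (`estimate_shift`): exhaustive integer-voxel
  search (default +-10 mm transaxial, +-20 mm axial) maximizing Dice
  between the nonAC-PET body support (>= 5% of maximum, largest
  6-connected component, internal holes filled — holes are filled
  against the lateral faces only, because the axial faces cut the
  torso) and the mu > 0 mask. Candidate shifts are visited in order of
  increasing magnitude so exact ties resolve toward the identity.
  Translation-only, because respiratory misalignment is reported as an
  axial offset.
* **Truncation completion** (`complete_truncation`): voxels inside the
  emission body support that are background in the mu-map receive the
  soft-tissue coefficient; nothing else changes. With reconstructed
  (blurred) support this also adds a thin soft rim at the true body
  edge — an accepted over-completion analogous to emission-derived
  attenuation estimates.

Tissue inversions and PMA bands are injected but deliberately not
corrected, mirroring clinical practice where these are hard to fix
retrospectively and sit away from the myocardium.

## Quantitation

Relative difference is RD = 100 x (corrected / original), evaluated
only where the original exceeds a validity floor (default 1% of its
maximum; the ratio is undefined at zero activity). The ratio is
computed before scaling so RD(x, x) is exactly 100 in floating point.
The myocardium is segmented at 42% of the regional maximum inside a
search box derived from phantom ground truth; `myo_stats` reports
SUVmean/SUVmax as plain reconstructed activity (no body-weight scaling
— only ratios are interpreted). Lung volume is the lung-coefficient
voxel count times the voxel volume; the test-retest flag fires when the
volume ratio deviates from 1 by strictly more than 10%.

The 17-segment polar map samples the wall along the long axis into
basal/mid/apical thirds (6+6+4 sectors, boundaries starting at the
anterior direction) plus the apical cap as segment 17, normalizes the
maximum segment to 100, and counts segments below 50 as defect. Given a
perfusion and a metabolism study, segments reduced in both are scar;
reduced in perfusion but preserved in metabolism are hibernating. The
50% segment-level threshold is a declared simplification of proprietary
clinical scorers; both thresholds are configurable.

## The cohort study

`run_study()` is a pure function of (config, master seed). Per subject:
one anatomy, two scans (perfusion-like and metabolism-like; an optional
LV sector defect with configurable hibernating/scar character), each
with independently drawn artifacts (default per-scan prevalences: STN
0.25, SMA 0.30, truncation 1.0, LSTI 0.05, FSTI 0.10, PMA 0.35) and a
per-scan axial misalignment (probability 0.55/0.70 for test/retest;
offset ~ N(7, 4) mm clamped to [-18, 12] mm). The emission data are
always attenuated by the *true* anatomy; reconstructions use the
artifactual map ("original") and the corrected map (fill where
susceptibility artifacts were recorded, re-align, complete truncation
where truncation was recorded). When no correction changes the map the
original reconstruction is reused, which also makes the no-artifact
case exactly RD = 100. `summarize_study()` emits the descriptive
tables: per-artifact frequencies with union semantics across the two
scans, RD summaries per artifact type, misalignment offsets (true vs
recovered), lung-volume test-retest, and polar-map scores. Cohort-level
statistics are descriptive only — the synthetic cohort is not a
reproduction of any patient population.

## Problem sizes and defaults

The reference grid is 128 x 128 x 64 at 2.6 mm isotropic. The study
runner defaults to a 128 x 128 x 32 slab (axial anatomy and the lung
target scale with the FOV), and reconstruction experiments use 16-slice
slabs around the LV; these sizes preserve every in-plane property of
the analysis while keeping a full cohort run to a few minutes.
`analysis/01_phantom.R` through `analysis/04_study.R` run the complete
workflow and write their tables under `results/`.

## Known limitations

* 2-D slice physics; no scatter, randoms, time-of-flight, or resolution
  modelling.
* The alignment surrogate registers translation only and needs a
  z-varying body outline; it would degrade on data whose support is
  axially homogeneous.
* EM partial-recovery bias at clinical iteration counts affects
  absolute wall means (see above); RD-based comparisons are much less
  sensitive because both reconstructions share it.
* The polar-map scorer is segment-level and threshold-based, not a
  reimplementation of clinical software.
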