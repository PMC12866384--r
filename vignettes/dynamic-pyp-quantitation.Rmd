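---
title: "Quantitative dynamic 99mTc-PYP SPECT/CT: models, phantom design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative dynamic 99mTc-PYP SPECT/CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pypquant)
```

## The measurement model

Cardiac amyloid imaging with [99mTc]Tc-pyrophosphate asks a simple
quantitative question: does the myocardium retain a bone-avid tracer above
blood-pool background? The package implements the measurement chain that
answers it on calibrated SPECT/CT:

1. **Calibration.** Reconstructed images arrive in counts/voxel/s. A
   uniform cylinder of known activity $A$ and volume $V$ gives the factor
   $cf = (A/V) / \bar{r}_{\mathrm{core}}$, where $\bar{r}_{\mathrm{core}}$
   is the mean count rate over the cylinder mask eroded by 2 voxel widths.
   The erosion guards against edge partial-volume spill-out; the emulated
   protocol does not specify the calibration VOI, so the 2-voxel core is a
   declared package convention. In the noiseless limit the round trip
   (counts $\to$ Bq/mL) is exact; with Poisson counting the error falls as
   $1/\sqrt{N}$ in the total core counts.
2. **Decay and dose bookkeeping.** All concentrations are decay-corrected
   to the pre-injection syringe-assay time with
   $C_{\mathrm{corr}} = C \cdot 2^{(t - t_{\mathrm{assay}})/T_{1/2}}$,
   $T_{1/2} = 360.4$ min. The net injected dose subtracts the
   post-injection residual, itself decay-referenced to the assay time:
   $ID = A_{\mathrm{assay}} - A_{\mathrm{res}} \cdot
   2^{(t_{\mathrm{res}} - t_{\mathrm{assay}})/T_{1/2}}$. Whether residual
   correction should reference the assay or the injection time is not
   fixed by the protocol text; assay-time referencing is the package
   convention, applied consistently on both the dose and the image side so
   the SUV is invariant to the choice.
3. **SUV and %ID/mL.** $\mathrm{SUV} = C \cdot W \cdot 1000 / ID$ (g/mL,
   unit tissue density assumed), and
   $\%ID/mL = 100 \cdot \mathrm{SUV}_{\mathrm{mean}} / (W \cdot 1000)$,
   reported as a percentage. The two compose to $100\,C/ID$, cancelling
   body weight — the property that makes %ID/mL the more stable group
   separator.
4. **Windows.** Synthetic statics average dynamic frames voxelwise over
   closed-open windows $[s, e)$, weighting each frame by its overlap
   duration, so results do not depend on how the window happens to be
   framed. The reporting windows are 10–25, 30–45 and 45–60 min plus the
   90- and 150-min static acquisitions; windows are named by their start.
5. **Segmentation.** The myocardial contour is derived from the 150-min
   image: within an anatomical shell prior, keep voxels above
   $k \times$ (left-atrial blood-pool mean on the same image), restricted
   to the largest 26-connected component. $k = 1$ by default — the exact
   threshold used clinically is not published, so $k$ is exposed and
   recorded in provenance. The rule only makes sense when the myocardium
   actually exceeds blood pool on the late image; for uptake-negative
   subjects the pipeline detects this (anatomical-VOI mean below the
   threshold, or a contour under 30 voxels) and falls back to the
   anatomical VOI, as CT-guided contouring would. Early-image VOIs are pure
   transfers of the late contour: independent re-contouring of early images
   is not attempted, since high blood pool makes the late threshold
   inapplicable there.
6. **Classification.** Blood-pool grade: positive iff myocardial SUVmean
   $\geq$ blood-pool SUVmean (ties positive, taking "equal to or greater"
   literally). %ID/mL rule: positive iff $\geq 0.003\%$; the boundary is
   classified positive and the threshold recorded, since the source only
   states strict inequalities on either side. Performance is scored against
   the cohort's group labels; Cohen's $\kappa$ uses marginal-product
   expected agreement, with perfect-but-degenerate agreement (all labels
   identical in both readers) defined as $\kappa = 1$ and flagged.

## What the phantom generator emulates

The generator's purpose is parameter recovery: its defaults *are* the
published group conditions, so that running the pipeline on a synthetic
cohort should return the published numbers up to sampling variability.

**Geometry.** Ellipsoid/cylinder compartments in physical mm coordinates
(myocardial shell enclosing the LV cavity, a left-atrial sphere, a spine
cylinder, an elliptic body) voxelised on a 64³ grid at 4.92 mm — the
emulated reconstruction voxel size; 48³ up to 128³ grids are supported and
compartment volumes are grid-independent up to voxelisation error.

**Kinetics.** Each tissue carries anchor points (time, group-mean SUV)
interpolated with a Fritsch–Carlson monotone piecewise-cubic (PCHIP):
the curve passes through every anchor, never overshoots beyond adjacent
anchors, and extrapolates as a constant. `stats::splinefun`'s `monoH.FC`
was rejected because it guarantees monotonicity only on monotone runs and
overshoots at local extrema such as the injection bolus peak. Anchors at
reporting-window midpoints (17.5, 97.5, 157.5 min) carry the published
group SUVmean values. Remaining anchors are package defaults constrained
by the qualitative findings: ATTR myocardium at or above blood pool from
10 min on; non-ATTR blood pool above myocardium always; bone rising to a
90-min peak, below the ATTR myocardium throughout (ATTR bone values were
never printed; its curve is qualitative-constraint-driven only, with CV
mirroring the published non-ATTR bone CV). Two further conventions matter:

* *Window consistency.* A value printed for a 15-min window is the
  duration-weighted window average, not a point sample. With a curved
  post-bolus decline, pinning the midpoint alone overshoots the window
  average by 2–4%. Each steep curve therefore has a "shoulder" anchor at
  10 min whose ordinate was solved once so that the 10–25 min window
  average equals the printed value exactly (e.g. ATTR myocardium 3.878 at
  10 min). This encodes the described kinetics — uptake peaking within the
  first 10 min, then near-stable.
* *Blood-driven early signal.* In the first minutes the myocardial VOI
  mostly sees the vascular bolus. The bolus anchors reproduce the
  published early %ID/mL (~0.007% at 2.5 min in ATTR-CM, ~0.002% at 1 min
  otherwise) and set the blood peak high enough that scaling the 0–5 min
  average to the late blood pool removes essentially all early
  myocardial-VOI signal in non-ATTR subjects (it clamps to zero) while
  retaining over half of it in ATTR subjects — the behaviour blood-pool
  subtraction is meant to expose.

**Inter-subject variability.** Each subject scales each tissue curve by a
log-normal factor whose CV matches the published group mean ± SD (0.20
ATTR myocardium, 0.33 non-ATTR myocardium, etc.; where the printed SDs
imply a time-dependent CV the first printed time point is used). Scales
are correlated across tissues on the log scale ($\rho = 0.8$), reflecting
shared subject-level factors (dose assay, weight normalisation, global
kinetics) on top of tissue-specific biology. Because the published cohort
is itself a selected population — group membership is defined by the
uptake pattern — subjects whose drawn scales violate their group's
defining ordering are resampled, and the latent log-means carry a
closed-form (Mills-ratio) offset such that the *accepted* population has
mean scale exactly 1 per tissue. The multi-time ordering constraint
reduces to a single linear constraint in log-scale space (scales are
time-constant), so the offset is exact, deterministic and needs no Monte
Carlo. Without it, rejection alone would bias the non-ATTR myocardial
group mean low by ~9%.

**Acquisition.** Voxels are filled with the true concentration at each
frame midpoint, decayed physically from the assay time; frames then pass
through optional isotropic Gaussian blur (12 mm FWHM when enabled — the
reconstructed resolution is not published — but disabled by default and
in all quantitative recovery runs, to avoid partial-volume bias that the
real study's resolution-recovery reconstruction is designed to suppress)
and Poisson resampling of frame counts at a sensitivity of
2×10⁻⁵ cps per voxel per Bq/mL, which yields clinically plausible count
levels (~10²–10³ counts/voxel in late statics for a ~900 MBq injection).
Weights and assay activities are sampled from the published group normals
truncated at ±3 SD; frame durations are a package choice (20 × 15 s over
0–5 min, 11 × 5 min over 10–65 min, 15-min statics at 90 and 150 min),
as the protocol figure fixes only the envelope.

**What it does not emulate.** No projection physics, attenuation, scatter,
anthropomorphic anatomy or motion; noise is count-statistics only, not
reconstruction-correlated; tissues are uniform within compartments. Tests
passing on this phantom therefore validate the *quantitation chain* —
calibration, bookkeeping, windowing, segmentation logic, classification —
not robustness to reconstruction artefacts or anatomical variability in
real images.

## Numerical and design choices

* Problem sizes: recovery runs use the 64³ grid and the full 33-frame
  schedule for 19 subjects; unit tests use 48³ and smaller synthetic
  arrays. A full cohort pipeline takes on the order of a minute.
* Degenerate inputs are errors, not warnings: empty VOIs, grid mismatches
  (no silent resampling), unit-tag mismatches (counts vs Bq/mL), empty
  segmentations (reported with the threshold used), zero blood-pool
  subtraction templates, non-positive net doses.
* Blood-pool subtraction scales the 0–5 min template by the ratio of
  left-atrial means (target over template) and clamps negatives to zero;
  the scale is exposed as a manual override since the reference protocol's
  exact rule is unpublished.
* Determinism: every random stage (subject sampling, Poisson noise,
  calibration noise) derives its seed from the master seed via a fixed
  integer mix; identical configurations and seeds give bit-identical
  cohorts, reports and CSVs. The persisted YAML configuration plus seed
  reproduces a run; a hash of the configuration is stamped into every
  output table.
* Group summaries use t-based 95% CIs (n ≤ 11 per group); single-subject
  groups get flagged undefined CIs rather than a value.
* Welch's t from summary statistics and Cohen's κ are implemented directly
  (they are part of the package's analysis surface) and cross-checked in
  the test suite against `stats::t.test` on reconstructed samples and
  `e1071::classAgreement`.

## Known limitations

* The %ID/mL threshold and all anchors describe one small pilot cohort;
  the generator reproduces that cohort's statistics, not population
  variability across scanners or body habitus.
* With blur enabled, partial-volume spill biases small-VOI recovery (the
  LA sphere most); quantitative recovery claims hold for the blur-off
  configuration.
* The blood-pool-threshold segmentation assumes uptake-positive late
  images; the anatomical fallback covers negatives but is a modelling
  choice, not a published rule.
* Per-voxel noise is independent Poisson; real iterative reconstructions
  produce spatially correlated noise, so VOI-variance behaviour on real
  data will differ from the $1/\sqrt{N}$ phantom behaviour.
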