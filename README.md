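# pypquant

Quantitative analysis of dynamic and static [99mTc]Tc-pyrophosphate
(99mTc-PYP) SPECT/CT for suspected transthyretin amyloid cardiomyopathy
(ATTR-CM), together with a seeded digital thorax-phantom cohort generator
that lets the whole pipeline run end to end without patient data.

99mTc-PYP is a bone-avid tracer that accumulates in amyloid-infiltrated
myocardium. Clinical protocols image 2–3 h after injection so that blood-pool
activity clears and the visual (Perugini) myocardium-versus-rib comparison
becomes interpretable. Absolute quantitation changes the question: once the
scanner is calibrated to activity concentration, myocardial uptake can be
compared against the blood pool, or against a fixed dose-normalised
threshold, within minutes of injection. This package implements that
quantitative chain for users studying early-imaging protocols: physicists
and analysts who need calibrated SUV metrics from dynamic SPECT series, and
methodologists who want a controlled synthetic cohort to exercise the
pipeline.

## What it computes

For a volume of interest (VOI) with mean activity concentration `C` (Bq/mL,
decay-corrected to the dose assay time):

* **SUVmean / SUVmax** `= C · W·1000 / ID` (g/mL), with body weight `W` (kg)
  and net injected dose `ID = A_assay − A_residual · 2^((t_res − t_assay)/T½)`
  (Bq), `T½ = 360.4` min for 99mTc.
* **%ID/mL** `= 100 · SUVmean / (W·1000)` — percent of the injected dose per
  millilitre of myocardium; the rule-in threshold is 0.003%.
* **Uptake ratios** LVmyo/LS (myocardium to spine) and LVmyo/LAbp
  (myocardium to left-atrial blood pool), which need no calibration.
* **Calibration factor** `cf = (A/V) / mean count rate` over the eroded core
  of a uniform cylinder of known activity `A` and volume `V`.
* **Synthetic statics**: duration-weighted voxelwise averages of dynamic
  frames over 15-min windows (10–25, 30–45, 45–60 min), comparable with the
  true 90- and 150-min static acquisitions.
* **Early classification**: positive if myocardial SUVmean ≥ blood-pool
  SUVmean (blood-pool grade) or %ID/mL ≥ 0.003% — scored as sensitivity /
  specificity / accuracy, with Cohen's κ for reader agreement and Welch's
  t for group comparisons from summary statistics.

The phantom generator fills a labelled thorax geometry (myocardial shell,
ventricular and atrial blood pools, thoracic spine, soft tissue) with
monotone-interpolated tissue time–activity curves anchored to published
group values, applies per-subject log-normal scales, physical decay,
optional Gaussian blur and Poisson count noise, and emits count-rate or
concentration images with the full frame schedule.

## Worked example

```r
library(pypquant)

report <- run_pipeline(run_config(n_attr = 8, n_non = 11, seed = 42,
  cohort = cohort_config(grid_shape = 64, units = "counts/voxel/s")))

subset(report$group_summary, metric == "suv_mean" & voi == "LV_myo" &
         window %in% c("10", "150"))[, c("group", "window", "n", "mean", "sd")]
#>       group window  n     mean        sd
#> 21     ATTR     10  8 3.409295 0.4647717
#> 23     ATTR    150  8 2.543879 0.3455334
#> 22 non-ATTR     10 11 1.353200 0.2984126
#> 24 non-ATTR    150 11 1.026428 0.2274858

report$performance$blood_pool_grade
#> Performance: sens 100.0%, spec 100.0%, acc 100.0% (TP 8 FP 0 TN 11 FN 0)
```

The group table mirrors the study design it emulates: at this seed the
simulated ATTR-CM myocardium sits near 3.4 g/mL at the 10–25 min window and
washes out only mildly by 150 min, while the non-ATTR group stays near
1.3 g/mL (cohort means scatter around the 3.86 / 1.24 g/mL group anchors
with the configured inter-subject spread) — and the
early blood-pool-grade rule separates the groups perfectly against the
generator's labels. `report$metrics` carries per-subject %ID/mL and uptake
ratios; `report$tac` the frame-by-frame time–activity curves
(`plot_group_tac(report$tac)` redraws the group curves).

A thin CLI over the same functions is installed at
`system.file("scripts/pyp-dynaquant.R", package = "pypquant")` with
`run`, `simulate` and `calibrate` subcommands.

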