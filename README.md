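# renalIRB

Quantitative MRI analysis of intrarenal backflow (IRB): what happens to the
kidney when the renal pelvis is pressurised during endoscopic procedures.
When intrarenal pressure (IRP) rises — as it does under forced irrigation in
ureteroscopy — pelvic fluid is forced retrogradely into the renal
parenchyma. If the irrigation fluid carries a gadolinium tracer, backflow
shortens tissue T1 and affected cortex turns dark on serial T1 maps, which
makes the process measurable: where, when, and how much of the kidney is
reached, as a function of pressure and time.

`renalIRB` is aimed at researchers analysing (or planning) pressurised-
irrigation MR studies of the kidney. It provides the complete analysis
chain plus a ground-truth digital kidney phantom, so every stage is testable
without any scan data:

* **Phantom** — multi-slice kidney (cortex / medulla / pelvis / muscle) whose
  cortex is partitioned into pyramid-like wedges; backflow is driven by the
  accumulated pressure and enters at the poles first
  (`makeKidneyPhantom()`, `simulateBackflow()`).
* **Rendering** — inversion-recovery magnitude series from the signal model
  *S*(TI) = *S*₀ |1 − 2 e^(−TI/T1)|, with Rician noise and per-TI rigid
  motion (`renderIRSeries()`).
* **Motion correction** — integer-pixel translation per inversion time by
  exhaustive cross-correlation of image *gradient* maps (gradients are
  robust to the contrast inversion across the null point)
  (`estimateMotion()`, `applyMotion()`).
* **T1 mapping** — pixel-wise least-squares fit of the magnitude model,
  multi-start over T1 with golden-section refinement of the profiled 1-D
  objective (`fitT1Pixel()`, `fitT1Map()`).
* **Backflow quantification** — affected cortex = relative T1 drop versus
  the pre-irrigation baseline scan, with a connected-component area filter;
  affected fraction, first-change detection, per-ROI T1 time courses
  (`segmentAffected()`, `affectedFraction()`, `detectFirstChange()`,
  `roiT1Series()`).
* **Pressure metrics** — pressure-log handling and the accumulated pressure
  impact AUPI = ∫ IRP dt (mmHg·min), exact trapezoidal integration
  (`accumulatedPressure()`), plus cohort endpoint summaries
  (`summarizeStudy()`).
* **Pipeline** — `runSyntheticStudy()` reproduces a full five-subject study
  from one validated configuration (`pipelineConfig()`), writing per-subject
  tables and a run manifest.

Gadolinium shortening follows the standard relaxivity model
1/T1 = 1/T1₀ + r₁·c (`concentrationToT1()`), and series round-trip to
NIfTI + JSON sidecars (`writeIRSeries()` / `readIRSeries()`).

## Worked example

Summarise the five-subject endpoint table shipped with the package
(first-change and end-of-irrigation time/pressure per subject):

```r
library(renalIRB)
rec <- read.csv(system.file("extdata", "study_endpoints.csv", package = "renalIRB"))
summarizeStudy(rec)
#> StudySummary: 5 subjects
#>   first_change_time_min: mean 15.4 (rounded 15, range 5..25)
#>   first_change_pressure_mmHg: mean 21 (rounded 21, range 16..25)
#>   end_time_min: mean 70.4 (rounded 70, range 60..80)
#>   end_pressure_mmHg: mean 43 (rounded 43, range 20..54)
```

So across this cohort, visible cortical change appeared on average 15
minutes into irrigation at a mean pressure of only 21 mmHg, and irrigation
ran for a mean of 70 minutes up to a mean final pressure of 43 mmHg.

Simulate one kidney under the 10→50 mmHg staircase protocol and recover the
backflow-affected cortical fraction from noisy scans:

```r
log <- staircaseLog()                       # 10..50 mmHg, 14 min per level
st  <- seq(0, 70, by = 5)                   # scans every 5 minutes
ph    <- calibrateWedgeOnsets(makeKidneyPhantom(3, c(48, 48), 8, seed = 1), log, st)
truth <- simulateBackflow(ph, log, st)
p     <- acquisitionParams(nSlices = 3)
maps  <- lapply(c(1, length(st)), function(k)
  fitT1Map(renderPhantomScan(truth, k, p, noiseSigma = 2, seed = k)))
cortex <- labelMap(truth) == 1
m <- segmentAffected(maps[[2]], maps[[1]], cortex)
affectedFraction(m, cortex)
#> [1] 0.6462715
sum(affectedTruth(truth)[15, , , ]) / sum(cortex)   # ground truth
#> [1] 0.6462715
```

The estimate at 70 minutes matches the phantom's ground truth exactly in
this run: roughly two thirds of the cortex is affected by the end of the
protocol. `runSyntheticStudy(pipelineConfig())` chains the same stages for
a whole cohort (including per-TI motion and its correction) and returns a
`StudySummary`; `inst/scripts/irb_run.R` wraps it for shell use.

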