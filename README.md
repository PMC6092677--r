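# tockysim

Simulation and analysis of Fluorescent Timer reporter flow cytometry, for
the Timer-of-cell-kinetics-and-activity (**Tocky**) approach to reading
transcriptional dynamics in single cells.

## The problem

A Fluorescent Timer protein (FT-Fast) is translated with an unstable blue
chromophore that matures spontaneously and irreversibly into a stable red
form. Driven by a gene of interest (the motivating system is *Foxp3* in
regulatory T cells), blue fluorescence marks transcription within the last
few hours while red fluorescence integrates it over about five days. Flow
cytometry of such reporters therefore encodes *when* and *how often* a gene
was transcribed — but only if the two-channel data are transformed and
calibrated correctly. This package is for immunologists and quantitative
biologists who need that analysis chain as tested, reproducible code, and a
matching simulator to validate it against known ground truth.

## The model and the transform

Per cell, the reporter follows a linear cascade with piecewise-constant
transcription *s(t)*:

```
dB/dt = s(t)·a − k_B·B          k_B = ln2 / 4.1 h   (blue loss)
dR/dt = m·B − δ_R·R             δ_R = ln2 / 122 h   (red decay)
```

solved in exact closed form (optionally with an explicit mRNA stage,
half-life 1.14 h). Measured events are thresholded against a negative
control (99.9% quantile), normalised per channel by the 97.5% quantile of
positive events, and mapped to polar coordinates in the Blue-Red plane:

```
Timer-Angle  θ = atan(red_n / blue_n) · 180/π   ∈ [0°, 90°]
Timer-Intensity  I = √(blue_n² + red_n²)
```

θ = 0° means brand-new transcription (no matured red), 45° the balanced
steady state of persistent transcription, 90° arrested transcription. The
angle partitions into five loci: **New** (0°), **NPt** (0–30°),
**Persistent** ([30°, 60°]), **PAt** (60–90°), **Arrested** (90°).
Half-life estimators (log-linear fluorescence decay, qPCR Ct slope) recover
the calibration constants from simulated blockade experiments:
cycloheximide (translation stop → blue halves every 4.1 h), red washout
(half-life 122 h), actinomycin D (Ct rises one cycle per mRNA halving).

## Worked example

Calibrate the blue half-life from a simulated cycloheximide series, then
analyse a mixed cohort the way a stained sample would be:

```r
library(tockysim)

dec <- simulateDecayExperiment("chx", sampleTimes = c(0, 2, 4, 6, 8, 12))
fitLogLinearHalflife(dec$blue_mfi)
#> HalfLifeFit (log_linear scale, n = 6)
#>   half-life: 4.1 h
#>   slope -0.1691, intercept 9.09, r = -1, r^2 = 1

cohort <- simulatePopulation(
  list(mixtureComponent(programNewOnset(0),  weight = 0.3, onsetAge = c(0, 4)),
       mixtureComponent(programPersistent(), weight = 0.5, onsetAge = c(100, 300)),
       mixtureComponent(programArrested(48), weight = 0.2, onsetAge = c(52, 76))),
  nCells = 2000, sampleTime = 0, seed = 42, label = "inflamed_skin_like")

thr <- deriveThresholds(cohort)          # from the paired negative control
thr
#> ChannelThresholds: blue 179.9, red 172 (quantile 0.999 of control 'control')

tf <- timerTransform(gateTimerPositive(cohort, thr))
summarizeSample(tf)
#> LocusSummary 'inflamed_skin_like': 1993 Timer-positive events
#>   fractions: New 0.055, NPt 0.249, Persistent 0.544, PAt 0.143, Arrested 0.009
#>   mean angle 36.46 deg, mean blue 5555, mean red 9.964e+04
```

The slope of ln(MFI) against time returns exactly the 4.1 h blue half-life
used to generate the series (r² = 1 on noise-free input). In the cohort,
the 30% recently induced cells show up as New/NPt mass, the persistent
expressors dominate the [30°, 60°] Persistent locus, and the small arrested
fraction sits near 90° — the locus fractions are the per-sample readout
that downstream statistics (`compareGroups()`, with the fewer-than-20-
positive-events exclusion rule) consume. `angleDensity()` gives the
boundary-corrected kernel density of angles, and `runTockyPipeline()` runs
the whole chain from a YAML config into a logged, seeded, reproducible run
directory.

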