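# erpbci

Simulation and decoding of seven-button P300 oddball brain–computer
interface (BCI) selections — the decoding stack behind HMD-based,
dry-electrode drone-control spellers used in virtual- and augmented-reality
studies, rebuilt as a fully offline, testable R package.

## Who this is for

BCI/EEG methodologists who want a reference implementation of the classic
P300 speller decoding chain that runs without hardware: a seeded synthetic
oddball-EEG generator stands in for the acquisition device, and the
published per-subject result tables of the modelled study ship as fixtures
so its summary statistics and significance verdicts can be recomputed
exactly.

## The model in brief

Seven buttons flash one at a time (100 ms on / 100 ms off, blockwise-random
order). The attended button's flashes elicit a P300: a positive ERP over
parietal sites peaking ≈ 400 ms post-stimulus. Decoding is:

1. re-reference 7 channels (Fz, Pz, Oz, P3, P4, PO7, PO8; 300 Hz) to the
   left ear;
2. bandpass 0.1–30 Hz (5th-order Butterworth);
3. epoch 0–1000 ms from each flash onset;
4. subtract each epoch's mean (baseline correction);
5. average 20 consecutive epochs per button (sliding window for training,
   one block online);
6. decimate to 100 Hz.

A shrinkage-regularized linear discriminant *f*(x) = wᵀx + b is trained on
the flattened 7 × 100 features (target vs. non-target), with w =
Σ*ᵣ⁻¹(μ₁ − μ₀) and Σ*ᵣ = (1 − ρ) Σ̂ + ρ (tr Σ̂ / p) I (analytic
Ledoit–Wolf ρ). For one selection, scores are summed per button and
argmax wins:  b̂ = argmax_b Σ_{epochs of b} f(x). Quality control flags
epochs whose max |amplitude| > 80 µV, selections with > 50% bad epochs, and
excludes subjects with ≥ 10 of 15 contaminated selections in either
environment. ERP analysis measures the P300 peak (max positive value, Pz,
250–600 ms) and compares environments with exact tie-aware Wilcoxon tests,
a Kolmogorov–Smirnov normality screen, and Benjamini–Hochberg FDR at
α = 0.05.

## Worked example

Recompute the published per-subject summaries from the packaged tables:

```r
library(erpbci)
tab <- reproduce_tables()
str(tab$accuracy)
#> List of 3
#>  $ mean_vr     : num 90.9
#>  $ mean_ar     : num 88.5
#>  $ mean_overall: num 89.7
c(tab$tests$accuracy$p, tab$tests$latency$p, tab$tests$amplitude$p)
#> [1] 0.630 0.264 0.378
```

The mean classification accuracy across the 17 retained subjects is 90.88%
in VR and 88.53% in AR (89.71% overall), and none of the paired VR-vs-AR
comparisons (accuracy, P300 latency, P300 amplitude) is significant at
α = 0.05 — the study's central "no environment difference" result.

Simulate and decode a complete experiment (training session, then 15 online
selections in each environment, QC, and ERP measurement):

```r
ex <- run_experiment(run_config(seed = 3))
ex
#> Simulated P300 selection experiment (seed 3 )
#>   accuracy: VR 93.33%  AR 100.00%
#>   P300 peak (VR): 410.0 ms, 4.68 uV;  (AR): 420.0 ms, 4.65 uV
#>   QC: 0 contaminated (VR), 0 (AR); excluded: FALSE
```

The simulated decoder operates at the 85–95% accuracy typical of this
design, and the measured peaks bracket the injected template (415.88 ms;
the ≈ 4.7 µV readout of a 5.09 µV bump reflects the whole-epoch baseline
subtraction, as documented in the vignette).

The same workflow is scriptable from a shell via `exec/erpbci` with
subcommands `simulate`, `preprocess`, `train`, `decode`, `qc`, `analyze`,
`reproduce-tables`, and `run`.

## Package layout

* `R/paradigm.R` — flash schedules, ERP template, noise model, synthesis
* `R/preprocess.R` — the six-stage pipeline
* `R/classify.R` — shrinkage LDA, summed-score selection, accuracy
* `R/qc.R` — epoch / selection / subject rejection rules
* `R/stats-tests.R`, `R/erp.R` — ERP measures and nonparametric statistics
* `R/io.R`, `R/cli.R`, `R/experiment.R` — file formats, CLI, end-to-end run
* `inst/extdata/table3.csv`, `table4.csv` — per-subject fixture tables
* `vignettes/erpbci-methods.Rmd` — models, assumptions, design decisions
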