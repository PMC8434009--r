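---
title: "Decoding seven-button P300 selections: models, pipeline, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding seven-button P300 selections: models, pipeline, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpbci)
```

## The problem

A P300 speller presents a small set of visual buttons that flash one at a
time in random order. The attended ("target") button is rare among the
flashes, so it elicits a P300 — a positive event-related potential (ERP)
peaking roughly 300–500 ms after the flash — while unattended flashes do
not. Summing a classifier's opinion over many flashes of each button and
picking the button with the largest total turns this weak single-trial
signature into a reliable discrete command, here one of seven drone
directions (forward, up, down, right, right turn, left, left turn) issued
from an HMD-mounted 7-channel dry-electrode EEG system (Fz, Pz, Oz, P3, P4,
PO7, PO8 at 300 Hz, left-ear reference) in virtual- and augmented-reality
settings.

`erpbci` is an offline re-implementation of that decoding stack. Because raw
EEG from the original experiment is not deposited, the package pairs the
decoder with a seeded synthetic-EEG generator, so every stage is testable
end to end, and ships the published per-subject result tables as fixtures so
the reported summary statistics and significance verdicts can be recomputed
exactly.

## The stimulation model

One *selection* consists of every button flashing `n_blinks` times (30 in
training, 20 online) with a 100 ms highlight and a 100 ms gap — a fixed
200 ms stimulus-onset asynchrony. Randomization is blockwise: each round of
seven flashes is an independent permutation of the buttons. This guarantees
exactly equal flash counts and bounds the spacing between successive target
flashes, which is the standard construction for spellers; a fully
unconstrained random order would occasionally starve or cluster a button.
Stimulus onset is defined as the instant the button toggles to its
highlight colour.

## The synthetic EEG generator

Each target flash adds a Gaussian positivity to every channel, scaled by a
fixed parietally-dominant topography (maximal at Pz). The template defaults
are the grand-average values of the modelled task: 5.09 µV peak at
415.88 ms. The full width at half maximum defaults to 60 ms: the published
per-subject latencies are all multiples of 10 ms, so the underlying averaged
peaks must be sharp enough to localize on a 10 ms grid, and a narrow bump is
what makes that localization well-posed after decimation to 100 Hz. Wider
settings are available and simply trade latency precision for a smoother
waveform.

The background noise has four additive, independently seeded components per
channel (including the reference, which carries noise only):

* **pink (1/f) noise**, 1.5 µV SD — the dominant low-frequency EEG
  background;
* **white noise**, 10 µV SD — electrode/amplifier noise, the realistic
  dominant term for dry electrodes;
* **an alpha rhythm**, 3 µV peak, with an *individual frequency drawn
  uniformly from 8.5–11.5 Hz* per channel and random phase. The frequency
  draw matters: a rhythm at exactly 10 Hz completes exactly two cycles per
  200 ms flash interval, so it would be phase-locked to every stimulus and
  would never average out, deterministically distorting the measured ERP —
  an instructive artifact of discretized paradigms, not of brains;
* **random-walk drift**, 1.5 µV·s^-1/2 — slow electrode drift, removed by
  the 0.1 Hz highpass.

On top of the stationary background, the *evoked response itself* varies
from flash to flash: a lognormal amplitude gain (mean 1, CV 0.5) and a
Gaussian latency jitter (SD 5 ms). This is deliberate and load-bearing:
with purely stationary noise, any level low enough to leave a 300-epoch
average clean enough for ±10 ms peak localization yields near-perfect
single-selection decoding, while real systems of this design decode at
85–95% yet still produce clean averages. Trial-to-trial response
variability is precisely the mechanism that decouples the two, because it
degrades 20-flash decisions but cancels in 300-flash averages. The default
noise level was calibrated once so that the full simulated decoder operates
at roughly 90% (85–95% across seeds) selection accuracy, and then frozen.

Occasional high-amplitude artifacts (100 ms half-sine transients, 120 µV, 2
per minute on a random single channel) emulate electrode pops and exercise
the rejection rules.

What the generator does **not** emulate: genuine scalp topography with
inter-channel noise correlation (channels are independent), visual evoked
responses to non-target flashes, eye blinks/saccades with frontal
topography, impedance non-stationarity across a session, or any difference
between the VR and AR settings beyond independent noise seeds. Passing
simulation tests therefore demonstrates the correctness and calibration of
the *pipeline*, not the field performance of any particular EEG device.

## The preprocessing pipeline

Six stages, applied in order to the continuous recording and then to
epochs:

1. **Re-referencing** — subtract the left-ear reference series from every
   channel.
2. **Bandpass 0.1–30 Hz, 5th-order Butterworth** — realized as a cascade of
   a 5th-order highpass at 0.1 Hz and a 5th-order lowpass at 30 Hz. A
   single 10th-order transfer-function bandpass with a 0.1 Hz edge at
   300 Hz is numerically unstable (pole magnitudes reach 1.00004, and
   forward–backward filtering diverges); the cascade has the same passband
   and each half is comfortably stable. Filtering is *causal*
   (forward-only) by default, mirroring what an online system can compute;
   a zero-phase (forward–backward) option exists for waveform analysis,
   where the causal filter's ~8 ms group delay would bias peak latencies.
3. **Epoching** — 0–1000 ms from each flash onset (300 samples at 300 Hz);
   epochs running past the end of the recording are dropped, not padded.
4. **Baseline correction** — subtract each epoch's whole-window mean per
   channel. With a 0 ms epoch start there is no pre-stimulus interval, so
   the full epoch serves as baseline. This removes the random amplitude
   offsets dry electrodes are prone to; it also subtracts a small fraction
   of the bump itself (~6% of the peak for a 60 ms-wide bump over 1 s),
   which is why recovered amplitudes sit slightly below the injected ones.
5. **Consecutive averaging of 20 epochs** within each (selection, button)
   group. Two readings of "continuously" are implemented: *sliding*
   (step-1 overlapping windows — 30 training flashes per button give 11
   averaged exemplars, a useful augmentation for training) and *block*
   (non-overlapping — the 20 online flashes per button give exactly the
   one averaged epoch per button that online decoding consumes). Training
   defaults to sliding, online decision to block; averaging never crosses a
   selection boundary.
6. **Decimation to 100 Hz** — keep every 3rd sample starting at the first.
   No additional anti-alias filter is needed because the 30 Hz lowpass
   already bounds the content well below the new 50 Hz Nyquist.

Every stage is linear, which the test suite exploits: the composed pipeline
must be elementwise equal to the manual chain, and linear combinations of
recordings must map to the same combinations of feature epochs.

## Classifier and selection rule

Feature vector = the flattened 7 × 100 averaged epoch (700 dimensions).
The classifier is two-class linear discriminant analysis with the pooled
covariance regularized by analytic Ledoit–Wolf shrinkage toward the scaled
identity. Shrinkage is not optional here: a training session yields on the
order of 10^2 averaged exemplars against 700 features, so the sample
covariance is singular and plain LDA is undefined. A Moore–Penrose
pseudo-inverse variant is provided for comparison. The discriminant is
oriented so larger outputs mean "more target-like"; the bias centres the
decision boundary between the class means (class priors are not used — they
are irrelevant to the selection rule, which compares sums across buttons).

For one online selection, raw discriminant outputs (not posterior
probabilities) are summed per button and the button with the largest sum
wins; exact ties break to the lowest button index, a deterministic
convention for an event of measure zero.

## Quality control

Three levels, with the comparison conventions taken literally from the
rejection narrative they implement: an epoch is *bad* iff its maximum
absolute amplitude across all channels and samples **strictly exceeds**
80 µV (exactly 80 is good); a selection is *contaminated* iff bad epochs
**strictly exceed** 50% of its epochs (70 of 140 is clean, 71 is not); a
subject is *excluded* iff **at least** 10 of the 15 selections in either
environment are contaminated. The epoch rule is applied to
baseline-corrected, pre-averaging epochs — before averaging dilutes
artifacts — and amplitude-flagged epochs are also excluded from ERP
waveform averages, as an analyst applying these rules would do.

## ERP measurement and statistics

The per-environment ERP is the pointwise mean of the single-flash target
epochs (up to 300 per environment), processed with the zero-phase filter
path. The P300 peak is automated as the maximum positive value on Pz (the
classic P300 site; a mean-parietal Pz/P3/P4 policy is available) within a
250–600 ms window, ties to the earliest sample; the original analysis read
peaks manually, which is not reproducible, so a deterministic rule is used
instead. Direction-wise summaries use the mean amplitude over 300–500 ms
inclusive.

Reported means and SDs use the population (divisor-*n*) SD convention,
because that is the convention under which the published per-subject
columns reproduce their own printed SD rows; reporting rounds half away
from zero to 2 decimals.

The paired and two-group comparisons use Wilcoxon tests authored in the
package: zero differences dropped, midranks under ties, and **exact**
two-sided p-values — computed by convolving the generating function of the
doubled midranks — whenever the usable sample is small (≤ 25 pairs for the
signed-rank test, combined n ≤ 20 for the rank-sum test), with a
tie-corrected normal approximation beyond. The standard library test cannot
compute exact p-values in the presence of ties or zeros, and the fixture
columns (latencies quantized to 10 ms, accuracies to multiples of 1/15) are
heavily tied, which is why the exact machinery exists; both tests are
verified against full enumeration oracles in the test suite. Normality
screening uses the one-sample Kolmogorov–Smirnov test against a normal with
the sample's own moments (asymptotic p); multiple comparisons use
Benjamini–Hochberg FDR; α = 0.05 throughout.

One transcription note: recomputing the preference-group cross accuracies
from the per-subject rows gives 85.47% (AR accuracy of the VR-preferring
group) and 89.33% (VR accuracy of the AR-preferring group), while the
source's prose assigns 89.33% and 85.48% the other way around — the two
values appear swapped there. `reproduce_tables()` reports the recomputed
values with a note rather than resolving the discrepancy. Likewise, a few
printed accuracies (95.00, 85.00, 90.00, 60.00) are not multiples of 100/15
and are stored verbatim in the fixtures.

## Determinism and numerical choices

Every random draw flows from an explicit integer seed; no function touches
the caller's RNG state. Stage seeds are derived from the master seed by a
two-pass generator hash: a plain linear combination of (seed, offset) is
*not* sufficient, because the generator's linear seed scrambling leaves
enough structure between related seeds that derived streams can be
statistically dependent — observable, for example, as above-chance
"decoding" of a target that was drawn from a sibling seed. Passing the
combined seed through two rounds of Mersenne–Twister output removes the
dependence; the chance-floor simulations sit inside the binomial band
around 1/7 across master seeds.

Other conventions: epoch boundary samples are inclusive on both ends of
measurement windows; decimation keeps sample indices 1, 4, 7, …; the
shrinkage intensity is clipped to [0, 1]; degenerate statistical inputs
(all-zero paired differences, zero variance) are signalled as errors, and
`compare_environments()` converts them to labelled "degenerate" entries
rather than fabricating a p-value.

## Validation design and problem sizes

The suite validates against three kinds of ground truth: published numbers
(fixture-table statistics, reproduced exactly), closed-form or enumerative
oracles (filter transfer functions, window averages, Fisher directions,
exact test null distributions, step-up FDR), and controlled simulation.
The simulation checks use: one full noise-free experiment (2 × 15
selections) for the 100% ceiling; 200 zero-response selections for the
chance floor, judged against the central 99% binomial band around 1/7; and
20 simulated subjects (15 selections, ~300 target flashes each) for P300
parameter recovery, requiring latency within ±10 ms and amplitude within
±20% in at least 18 of 20. These sizes give the stochastic checks enough
resolution to fail informatively while keeping a full test run around a
minute.

## Known limitations

* The simulator's noise is channel-independent and stationary within a
  recording; real dry-electrode EEG is neither.
* The VR/AR contrast exists in the simulator only as independent seeds, so
  cross-environment comparisons on simulated data test the machinery, not
  any environment effect.
* The automated peak rule measures the maximum of a noisy average; its
  amplitude estimate is biased slightly upward by noise and slightly
  downward by baseline subtraction and latency jitter (net ≈ −8% under
  defaults).
* Self-predicted-vs-actual accuracy correlation is exercised on synthetic
  data only; the underlying per-subject self-predictions were published
  only as a figure, not as numbers.
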