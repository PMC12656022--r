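---
title: "Detecting freezing of gait from ankle accelerometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting freezing of gait from ankle accelerometry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fogcue)
```

## The detection problem

Freezing of gait (FoG) interrupts the rhythmic stride/stance pattern of
walking — dominant spectral peaks near 1 and 2 Hz in the ankle acceleration
magnitude — and replaces it with lower-amplitude trembling concentrated in
the 3–8 Hz band. Standing produces neither. `fogcue` classifies 4 s windows
of a single ankle sensor's filtered acceleration magnitude as FoG or normal
movement, window by window, every 0.5 s. The single distal sensor is a
deliberate design point: shank-worn accelerometers capture lower-limb
trembling most strongly, and one sensor is what a deployable cueing wearable
carries.

The pipeline's assumptions, stated plainly:

* gait dynamics live below 15 Hz; everything above is treated as noise;
* the 0.5–3 Hz / 3–8 Hz band dichotomy captures the locomotion-versus-
  trembling contrast (the Freezing Index is their power ratio);
* a window is a meaningful unit of decision — episodes shorter than about
  half a window are at the resolution limit;
* annotation follows the DAPHNet convention: 0 outside the experiment,
  1 movement without freezing, 2 freezing.

## Windowing and labeling

Windows are 4 s (256 samples at 64 Hz) advancing by 0.5 s (32 samples,
87.5 % overlap): long enough for sub-Hz spectral resolution (bin width
64/256 = 0.25 Hz), short enough to catch episodes of a few seconds. The
window-level label rule is not prescribed by the annotation scheme itself,
so the package makes a choice and exposes it: a window touching **any**
annotation-0 sample is excluded; otherwise it is FoG when at least half its
samples are annotated 2 (`label_threshold`, default 0.5; the exact 50 % tie
resolves to FoG so boundary windows are not silently biased toward the
majority class). Majority labeling keeps episode-boundary windows balanced
between the classes; the threshold is configurable for sensitivity
analyses.

Timestamps are used for gap detection only: a gap longer than two sample
periods splits the recording into contiguous blocks that are windowed
independently, so no window straddles a dropout. No resampling is
performed.

## Filtering

The 15 Hz low-pass is realized as a 4th-order Butterworth. Offline it runs
forward–backward, which doubles the effective order and removes group
delay; the zero-phase pass uses odd-reflection padding with steady-state
initial conditions, so a constant input passes through exactly (a naive
double pass would ring at the edges). The streaming detector necessarily
runs the same coefficients causally, single-pass, with persistent filter
state across packets. This is the one place batch and streaming legitimately
differ; the equivalence test therefore compares streaming against a batch
run with the causal filter, where agreement is exact to the last bit.

## Features

Every spectral feature shares one estimation convention: remove the window
mean, apply a periodic Hann taper, take a length-256 DFT, keep the one-sided
half. The Hann taper bounds leakage that would otherwise let strong 1–2 Hz
gait lines bleed across the 3 Hz band edge and corrupt the Freezing Index;
the periodic (denominator-N) form confines an exact-bin tone to its bin and
the two adjacent ones. Power is normalized so the one-sided bins sum to the
tapered signal's mean square (Parseval), amplitude so an exact-bin unit sine
reports magnitude 1.

The default 14-feature vector, in frozen order: `fi`, `hfp_hz`, `mhfp`,
`shfp_hz`, `mshfp`, `min`, `max`, `median`, `kurtosis`, `skewness`,
`entropy`, `zcr`, `mcr`, `sum_mag`; the 17-feature variant appends `mean`,
`rms`, `std`. The order is recorded in trained models and feature CSVs to
prevent train/serve skew. Numerical choices worth knowing:

* **Freezing Index** — freezing-band power over locomotion-band power, with
  ε = 1e−12 guarding the denominator: a standing window with near-zero
  locomotion power maps to a large finite ratio, never infinity. Band edges
  are inclusive; the shared 3 Hz bin is counted in both bands.
* **Spectral peaks** — local maxima (strictly greater than both neighbor
  bins) of the amplitude spectrum within 0.25–15 Hz, ties toward lower
  frequency. With a Hann taper an exact-bin tone makes its immediate
  neighbors exactly half its height, so when fewer than two local maxima
  exist the fallback picks the largest bins *not adjacent* to an already
  selected peak; an all-zero spectrum reports (0.25 Hz, 0) for both slots.
* **Moments** — population estimators; kurtosis is excess (Gaussian → 0);
  zero-variance windows report 0 for both shape statistics.
* **Crossing rates** — the window is a nonnegative magnitude, so a raw
  zero-crossing rate would be degenerate. ZCR is counted on the linearly
  detrended window, MCR about the raw window's own mean, keeping the two
  features distinct. A crossing is a transition of the positive-part
  indicator, divided by L−1.
* **Entropy** — "entropy" admits several readings (sample, histogram,
  spectral); the package implements normalized spectral entropy (Shannon
  entropy of the DC-excluded power spectrum over log bin count, range
  [0, 1]) because it directly measures the tone-versus-broadband contrast
  the other spectral features rely on.

Mean, RMS and STD are excluded from the default classifier input: on a
standardized magnitude signal they are nearly collinear with the retained
amplitude statistics. They remain available (`include_discarded = TRUE`),
and the importance analysis runs on the 17-feature set by default so their
contribution can be inspected rather than assumed.

## Classifier and hyperparameter search

Features are z-scored with center/scale fitted on training rows only
(zero-variance features get scale 1); RBF kernels on raw mixed-unit
features would be dominated by whichever feature has the largest numeric
range. The SVM grid is C ∈ {0.01, 0.1, 1, 10, 100} ×
γ ∈ {0.001, 0.01, 0.1, 1}, each point scored by stratified seeded 5-fold
cross-validated mean F1 with FoG positive (no predicted positives counts as
F1 = 0); ties break toward smaller C, then smaller γ — the simpler model.
The winner is refit on the full training set. Class imbalance is handled by
stratification only; an inverse-prevalence weighting flag exists but
defaults off. One subtlety: libsvm orients its decision values toward
whichever class appears first in the training rows, so the package
reorients scores from the decision-value metadata — positive always means
FoG.

## Evaluation regimes

* **LOPO** (patient-independent): one grid-searched model per held-out
  subject, trained on the pooled windows of all others. Subjects lacking a
  class in their held-out data are flagged rather than dropped silently;
  subjects with no FoG windows at all cannot be scored and are excluded
  upstream.
* **Patient-specific**: the 75/25 stratified split is realized as a
  repeated stratified 4-fold partition — each fold serves once as the 25 %
  test split, so class proportions in every split sit within one window of
  the subject's prevalence — with 5 repeats by default, metrics averaged
  over repeats.
* **Importance**: the classifier is kernel-based and has no native
  importances, so the package uses permutation importance — held-out F1
  drop when one feature column is shuffled, averaged over repeats, clipped
  at zero, normalized to a per-subject maximum of 1.

Fold assignment deals shuffled within-class indices round-robin, is seeded,
and is asserted to partition the windows exactly — no window can appear in
both sides of the same fit.

A note on comparing the regimes: with the simulator's default,
strongly separable conditions both regimes saturate near perfect scores and
their ordering is noise. The property that patient-specific training is at
least as sensitive as LOPO is therefore tested on deliberately
heterogeneous cohorts in which one subject trembles in an atypical band
straddling the 3 Hz locomotion edge — the mechanism (FoG signatures differ
between patients) that makes individually trained models win in practice.

## The simulator: what it emulates, what it does not

`simulate_subject()` composes three regimes with 0.25 s cross-fades (so
regime changes are not step discontinuities a classifier could key on):

* **gait** — gravity plus a stride sinusoid (default 1 Hz, 0.3 g) and a
  stance harmonic (2×, ratio 0.6), both riding the vertical axis so the
  Euclidean magnitude carries them at first order (an oscillation
  orthogonal to gravity enters the magnitude only at second order and
  frequency-doubled), with smaller cross-talk copies on the horizontal
  axes;
* **FoG** — gravity plus 2–3 seeded sinusoids drawn from 3–8 Hz at half
  the gait amplitude (`fog_amp_scale` = 0.5): power shifts into the
  freezing band while overall magnitude drops;
* **standing** — gravity plus noise only.

Episode durations are drawn uniformly from 0.5–40.5 s (the annotated
episode-duration range of the public ankle-sensor dataset the file dialect
comes from) and placed without overlap; white noise (0.02 g) covers all
axes; 2 s lead-in/lead-out margins carry annotation 0; thigh and trunk
channels are attenuated ankle copies plus noise, present only for format
completeness. Defaults describe a 300 s trial with 4 episodes and 15 %
standing — roughly a 5-minute walking task with a realistic double-digit
window prevalence. Samples are rounded to integer milli-g, matching the
file dialect and making write→read round trips exact.

What the simulator does **not** model: biomechanical gait shape (heel
strikes, asymmetry), tremor and dyskinesia confounders, the patient-specific
"small pulses" some freezers show, sensor drift, or any noise structure
beyond white. Passing tests on simulated cohorts therefore demonstrate that
the pipeline's machinery is correct and that it separates the spectral
signature it was designed around — they do not certify clinical performance
on real patients, where class overlap is far larger. The DAPHNet replication
harness (`inst/scripts/replicate_daphnet.R`) exists for that purpose and
reports, rather than asserts, its cohort means, since the original
window-labeling rule, entropy definition, feature scaling and split seeds
of published pipelines are not fully specified.

## Streaming and cueing

The stream consumes raw triaxial packets, maintains the causal filter state
and a 256-sample ring, and classifies after every 32nd sample once the ring
fills: decision *i* lands at sample 256 + 32·i. Under the majority label
rule the earliest window that can go FoG-positive ends ~2 s after episode
onset, plus up to one 0.5 s step of quantization — an intrinsic algorithmic
latency floor independent of hardware. The cue switches on at the first
positive decision and off after 2 consecutive negatives (hysteresis so the
cue spans an episode rather than flickering); the stimulus itself is a pure
function of time since activation: on iff `frac(t · rate_hz) < duty`, with
defaults 1 Hz and 0.5 chosen as a mid-range setting of the device's
exposed frequency control. The packet codec is newline-delimited text with
an additive checksum — debuggable and loss-tolerant in the spirit of the
original UDP telemetry; no real sockets are in scope.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run entirely on simulated data:
oracle comparisons over 1000-window corpora, 2-minute single-subject
fixtures for classifier and streaming checks, a 4-subject × 300 s cohort
(≈ 2300 windows) for the end-to-end LOPO and patient-specific runs, and
10 draws of 3-subject × 90 s heterogeneous cohorts for the regime
comparison — sizes at which every result in the README is reproduced in
about two minutes on a laptop core. All randomness (simulation, folds,
splits, shuffles) flows from explicit integer seeds; the same seed
reproduces recordings bit-for-bit and reports byte-for-byte.

## Known limitations

* Window-level metrics only; episode-level scoring (onset latency against
  video annotation, episode counts) is out of scope except for the
  geometric latency helper.
* The pipeline assumes 64 Hz input; other rates work arithmetically
  (window lengths must stay whole samples) but the defaults' bin widths
  and band edges were chosen for 64 Hz.
* Whether to feed the classifier milli-g or g matters only for
  scale-carrying features (the Freezing Index is scale-invariant);
  the package standardizes on g at load time.
* No probability calibration: scores are signed margins, monotone but not
  probabilities.
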