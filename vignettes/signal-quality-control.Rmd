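---
title: "Signal quality control for ECG and PPG waveforms with sqikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal quality control for ECG and PPG waveforms with sqikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sqikit)
options(sqikit.quiet = TRUE)
```

## The problem

Continuously recorded electrocardiograms (ECG) and photoplethysmograms
(PPG) — especially from low-cost wearables — are riddled with artifacts:
loose sensor contact, motion, transmission dropout. Downstream analyses
(heart-rate variability, waveform machine learning) are only as good as the
segments fed into them, so the practical first step is segment-level
quality control: cut the recording into fixed windows, summarize each
window with scalar *signal quality indices* (SQIs), and apply explicit
accept/reject threshold rules.

`sqikit` implements that workflow end to end: format readers (EDF, WFDB,
delimited text) into a common `waveform_record`; preprocessing (zero-phase
bandpass filtering, invalid-signal marking, segmentation); seven
interchangeable beat detectors; a catalogue of statistical, HRV-based and
morphology-based SQIs; and a JSON-configurable rule engine with two
threshold-derivation procedures. A seeded synthetic generator with ground
truth supports testing and calibration without patient data.

## Pipeline and defaults

The extraction pipeline is: bandpass filter → invalid marking →
segmentation → per-segment SQI computation.

* **Filter.** Butterworth order 4, applied forward–backward
  (`signal::filtfilt`) so beat locations are not phase-shifted. Default
  bands: 0.5–8 Hz for PPG (pulse fundamental plus harmonics), 0.5–40 Hz for
  ECG (QRS content). Chebyshev-I and elliptic designs are available where a
  sharper transition matters.
* **Invalid marking** runs on the *raw* signal: non-finite samples, runs of
  an exactly repeated value ≥ 2 s, and zero runs ≥ 2 s are flagged. The 2 s
  default must exceed any plausible diastolic plateau, and both thresholds
  are configurable. Invalid samples are flagged in place, never dropped, so
  sample indices always align with the recording.
* **Segmentation.** Non-overlapping 30 s windows (long enough for HRV
  statistics, short enough that one artifact does not contaminate many
  rows); the trailing partial window is dropped so all rows have equal
  support. With the default `invalid_tolerance = 0`, any invalid sample
  invalidates its segment; invalid segments are kept as all-NA rows, which
  the rule engine rejects through each rule's `na_decision`.

## Beat detection

Seven deterministic detectors are provided (ids 1–7): adaptive amplitude
threshold with a decaying running maximum; count-origin validation of
monotone ascent/descent run lengths; a deterministic two-cluster split of
local-maximum amplitudes (2-means initialized at the min and max amplitude,
so no RNG is involved); a slope-sum transform with threshold crossing and
local search; two moving averages (0.111 s beat-scale vs 0.667 s
segment-scale) defining blocks of interest; local maxima under prominence
and minimum-distance constraints; and the Billauer alternating max/min
delta tracker. Detector 5 is the default for PPG. For ECG, detection runs
on a squared-derivative, moving-window-integrated transform of the signal
and each detection is refined to the local signal maximum within ±50 ms.

All detectors share a refractory period (default 0.3 s, a 200 bpm ceiling)
and break amplitude ties toward the earliest index. Thresholds are relative
(fractions of running maxima, signal range, or mean squared amplitude), so
detectors 1, 3, 5, 6 and 7 are invariant to positive amplitude scaling —
a property the test suite asserts, along with translation equivariance.
Since the detectors only see amplitudes, detectors 2 and 5 additionally
screen candidates against the strongest candidate (midrange and quarter of
the maximum squared excursion, respectively) so that pronounced diastolic
waves at slow heart rates are not double-counted; the screens are relative,
preserving scale invariance.

Troughs are the minimum strictly between consecutive peaks (earliest on
ties); beats are cut trough-to-trough, resampled to a common length and
baseline-shifted to start at 0. Beats shorter than 0.25 s or longer than
2 s are discarded as segmentation failures.

## The SQI catalogue

**Statistical (per segment or per beat).** Perfusion
`(max y − min y)/|mean x| × 100` with `y` filtered and `x` raw; skewness and
kurtosis as 1/N-normalized standardized moments (kurtosis is reported raw,
Gaussian → 3, because the defining formula carries no −3 term); energy
entropy `−Σ p log p` with `p = x²/Σx²`; SNR as the variance ratio of a
moving-average decomposition (the two parts reconstruct the input exactly);
relative spectral power (1–2.25 Hz over 0–8 Hz by default); zero and mean
crossing counts with carry-forward of the previous sign at exact reference
hits, making counts deterministic on quantized signals.

The entropy formula is scale-dependent and unbounded unless the signal is
first normalized to unit energy; `sqikit` always applies that
normalization, so the index lies in `[0, log N]` and is amplitude-scale
invariant. This normalization is an explicit design choice, stated here
because the bare formula omits it.

**HRV-based.** Peak indices become NN intervals in ms; ectopic removal uses
either the Malik 20% rule or a running-median 30% rule. The Malik rule
compares each interval to the *last kept* interval (the convention of the
established HRV packages): comparing to the raw predecessor would discard
the normal interval that follows a single short ectopic one. Time-domain
measures follow the standard definitions (sample n−1 standard deviations;
pNN50/pNN20 denominators are the number of successive differences, since
each comparison is per-difference). Frequency-domain measures interpolate
the tachogram with a cubic spline at 4 Hz and integrate Welch PSD over the
conventional bands VLF [0.003, 0.04), LF [0.04, 0.15), HF [0.15, 0.4) Hz;
they require ≥ 60 s of intervals and are therefore NA on default 30 s
segments unless segmentation is lengthened.

**Morphology and agreement.** MSQ is the greedy one-to-one agreement
fraction between two different detectors within ±0.15 s (below half the
shortest physiological beat); a second variant, `msq_shift_sqi`, runs the
*same* detector on the segment and its 1 s-shifted copy, probing detection
stability. Both variants exist because both are meaningful and they answer
different questions. The correlogram SQI reports the first lags and
prominences of the normalized autocorrelation — a clean pulse shows its
beat period as the first peak. DTW template matching aligns each beat
(zero-mean, unit max-abs) against an idealized template — a double-Gaussian
pulse for PPG, a five-Gaussian P-QRS-T sum for ECG — with |a−b| local cost,
full alignment and no warping window (beats are ≤ a few hundred samples, so
the exact computation is affordable), reporting accumulated cost per path
step. QRS energy is the relative power [5, 15) over [5, 40) Hz; amplitude
ratios report per-beat peak-to-nadir (ECG) or systolic/diastolic ratio
(PPG, NA when no diastolic shoulder exists after the systolic peak).

Per-beat SQIs are aggregated per segment as mean, median and standard
deviation (`kurtosis_mean`, `entropy_std`, `dtw_median`, ...).

**Spectral conventions.** All band integrals use half-open bins
`[lo, hi)` over a Welch estimate (Hann window, 50% overlap, per-segment
mean detrend; 4 s windows for waveforms). Half-open bands tile the axis
without double-counting shared edges, and with the default grid the
white-noise expectation of the relative-power index equals the continuous
bandwidth ratio.

## Rules and thresholds

A rule is an ordered list of `(operator, threshold, decision)` boundaries
for one SQI; the first matching boundary wins and an unmatched value is
accepted. Rulesets evaluate rules in a stated order with AND semantics:
the first rejecting rule short-circuits (and is recorded), and a segment is
accepted only if every rule accepts. This makes classification monotone —
adding a rule can only move segments from accept to reject — which the
suite verifies over 1000 random rulesets. Missing values fall through to
each rule's `na_decision`, defaulting to reject: in quality control, the
cost of analyzing garbage exceeds the cost of discarding a usable segment.

Two threshold-derivation procedures are provided: the q-th percentile
(default 95) of the accept-class values, and a brute-force grid search over
pooled-value quantiles (step 0.05) and both rejection directions,
maximizing balanced accuracy — chosen as the per-threshold objective
because labelled quality datasets are typically imbalanced. `pair_search`
evaluates every unordered pair of candidate SQIs as a two-rule AND ruleset
and ranks pairs by the ROC AUC of their combined (min-quantile) score.

The shipped template ruleset (`inst/extdata/ruleset_template.json`) bounds
energy entropy below by 5 (degenerate concentration), kurtosis above by 6
(spike-dominated segments), detector agreement (MSQ ≥ 0.8), the Malik
ectopic fraction (≤ 0.2) and the first correlogram prominence (≥ 0.3, i.e.
the segment must be visibly periodic). The thresholds were chosen as round
values sitting far from the clean-segment distributions of the synthetic
study conditions and on the physiologically implausible side of each index.

## The synthetic generator

`synth_record` draws beat intervals as Gaussians around `60000/HR` ms
(default jitter 25 ms, a realistic resting sinus variability), truncated at
±40% of the mean — a deliberate simplification over autoregressive HRV
models that keeps the ground truth exact; LF/HF tests add explicit
sinusoidal interval modulation instead. Each beat renders the PPG or ECG
template across its interval; white noise (default sd 0.02 against unit
beat amplitude) and sinusoidal baseline wander (default amplitude 0.1 at
0.2 Hz, a respiratory scale) are added. Artifacts — flatline, zero
dropout, spike bursts, added noise — are injected over stated spans and
recorded in the ground truth.

What the generator does *not* emulate: beat-to-beat morphology variability,
pathological rhythms, motion artifacts correlated with the pulse, and
device transfer functions. Passing tests therefore demonstrate correctness
of the algorithms under controlled quasi-periodic conditions, not clinical
performance on any particular device; thresholds for real data should be
re-derived from labelled segments with `derive_ruleset`.

## Numerical choices and degenerate inputs

* Sample spans are half-open `[start, end)` with 0-based starts; peak and
  trough indices are 1-based positions within a segment's sample vector.
* Ties: earliest index wins (peaks, troughs, equal-cost DTW steps resolve
  in a fixed match/insert/delete order; threshold search prefers the
  smallest threshold and reject-below).
* Resampling is Fourier-based (spectrum truncation/zero-padding), which is
  delay-free; the Nyquist bin is split or folded to keep real signals real.
* Constant segments: no peaks, zero crossings 0, moments and entropy NA,
  DTW NA, correlogram NA — degeneracy propagates as NA, never as 0.
* All randomness (generator, spike placement) flows through explicit
  integer seeds; identical specs are bit-identical.
* Test problem sizes: 30–600 s records at 100 Hz, heart rates 40–180 bpm,
  oracle batches of 100 random signals — small enough to run the whole
  suite in well under a minute per module while exercising every code
  path.

## Known limitations

EDF writing quantizes to 16 bits over the observed amplitude range and
requires an integer sampling rate; WFDB support covers single-`.dat`
records in formats 16 and 212. ECG detection assumes upright R waves.
`hrv_freq_sqi` needs ≥ 60 s spans. The rule engine is deliberately
binary — no probabilistic scores — mirroring its role as a transparent,
auditable gate in front of downstream analysis.
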