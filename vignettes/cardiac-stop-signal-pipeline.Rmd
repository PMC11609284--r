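---
title: "Methods: simulating and analysing cardiac-coupled stop-signal experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing cardiac-coupled stop-signal experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cardiostop` is built around one idea: every stage of a cardiac-coupled
stop-signal analysis should be checkable against data whose ground truth is
known exactly. This vignette documents the models, the tunable parameters,
the numerical conventions, and the design decisions taken where the
procedure itself left a choice open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. The cardiac process

RR intervals are a lag-1 autocorrelated Gaussian process
RR_i = μ + x_i, x_i = φ·x_{i−1} + ε_i, with μ = 60000/HR ms and the
stationary variance v chosen so that the expected root mean square of
successive differences, RMSSD = √(2·v·(1−φ)), equals the request. This is
the simplest process with independently controllable mean heart rate and
RMSSD. Defaults: HR = 58.2 bpm, RMSSD = 53.5 ms — resting values for a
healthy young adult sample — and φ = 0.3, a mild short-range correlation so
consecutive beats are not independent. Non-positive draws are resampled;
combinations whose implied spread approaches the mean RR (stationary SD
above μ/3) are rejected as a parameter error. What this process does *not*
emulate: respiratory sinus arrhythmia periodicity, long-range (fractal)
correlations, or ectopic beats. Tests that pass on this process therefore
certify the analysis code, not robustness to arrhythmia.

The synthetic ECG renders one piecewise-Gaussian QRST complex per beat
(Q −30 ms/−120 µV, R 0 ms/1000 µV, S +30 ms/−180 µV, T centered at 250 ms
with 50 ms width and 250 µV, T timing scaled by √(RR/1000)). The per-beat
end-of-T estimate used to split systole from diastole is T-center + 2
T-widths = 350·√(RR/1000) ms (clamped below 0.9·RR). The real criterion for
locating T-end on measured ECG is not part of this package's claims; the
rule here is a documented, heart-rate-adaptive stand-in that makes phase
coding exactly testable.

## 2. Task scheduling and the staircase

Each trial: arrow display with one distractor-movement onset per heartbeat
at the condition's offset (systole R+290 ms, diastole R+0 ms) plus Gaussian
trigger-latency jitter (SD 70 ms by default, reproducing the realized
precision of hardware-triggered designs); go-cue uniform in 2.9–4.5 s after
trial start subject to at least three (at most five) heartbeats before it;
1.5 s response window; stop-signal at the staircase SSD on stop trials,
shown up to 1 s; 1 s feedback; 0.5 s inter-trial interval. Analytic trial
spans are therefore 5.4–7.0 s plus ITI. The rule for reconciling the cue
window with the heartbeat constraint at extreme heart rates is a package
decision: the cue is redrawn (up to 100 times) and, failing that, the
window is extended to the third beat + 50 ms and the trial flagged.

The staircase starts at 200 ms, moves ±50 ms (up after a correctly
withheld response, down after a commission) and is capped at 750 ms. No
floor is part of the design constants; we floor at 50 ms — one step above
zero — so the stop-signal never precedes the go-cue. Separate trackers per
condition never interact.

Sessions default to 3 blocks (systole, diastole, no-distractor;
counterbalance order selectable) × 150 trials (100 go / 50 stop).

## 3. The behaving agent and SSRT

Go finishing times are ex-Gaussian (defaults μ = 400, σ = 40, τ = 60 ms);
the stop process has constant latency (default 220 ms); a stop trial
yields a response iff the go process beats SSD + SSRT. Go responses are
censored at the 1.5 s window (coded as omissions), and an independent
omission probability (default 8%) emulates attentional lapses.

SSRT uses the integration method: sort the n go RTs, take the RT at rank
⌈n·p(respond|stop)⌉, subtract the central tracked SSD. Conventions we had
to fix:

* **Omitted go trials** are assigned the maximum observed RT before
  ranking (switchable to dropping them). Without the correction, omissions
  deflate the RT distribution and bias SSRT down.
* **Central SSD**: the *mean* tracked SSD by default. The median of a
  ±50 ms staircase walk snaps to the step grid and can sit half a step
  away from the delay that actually realized p(respond|stop), which
  biases recovery visibly (the mean does not); the median SSD is still
  reported as a descriptive statistic, and the choice is an argument.
* **Non-integer n·p**: ceiling (conservative quantile convention).

## 4. The EEG forward model

EEG is strictly linear: channels × time = Σ_k w_k · s_k(t) + noise, one
term per template. A template is a spatial pattern (Gaussian falloff
around a peak electrode on the packaged 64-channel 10-10 montage, 9-cm
head sphere), a raised-cosine waveform on a half-open latency window, and
per-condition gains. Defaults (amplitudes in µV at the peak electrode,
gains dimensionless):

| template | locks to | window (ms) | peak | condition gains |
|---|---|---|---|---|
| HEP | every R-peak | 300–400 | 2 | diastole 0.7, others 1 |
| P2 | distractor movement | 200–300 | 5 | systole 0.7, diastole 1 |
| N2 | stop-signal | 200–300 | −4 | diastole 0.65, others 1 |
| P3 | commission feedback | 300–400 | 6 | systole 1.4, others 1 |

The gain directions implement the qualitative pattern under study
(distractor-evoked P2 larger at diastole; HEP and stop-N2 reduced at
diastole; commission-P3 enhanced at systole); magnitudes are simulation
choices at the scale such components show in practice (sub-µV to a few
µV), not measured values. The cardiac field artifact is one more template:
an R-locked sharp QRS-like deflection plus a slow T-range bow (peak 15 µV)
with a left–right scalp gradient, identical across conditions. Sensor
noise is white Gaussian (default SD 10 µV per sample). Real EEG background
is temporally and spatially correlated (1/f, alpha); white noise makes
epoch-count arithmetic transparent but means the simulator does not test
robustness to structured noise.

Event times are snapped to the sample grid when rendered — as a digital
acquisition system does — so with zero noise every analysis window
recovers the injected waveform *exactly*, which the tests exploit.

## 5. Analysis conventions

* Windows are half-open `[start, end)` ms, so a window holds exactly
  (end−start)·fs/1000 samples. R's native 1-based indexing is kept for
  storage; only the window convention is fixed. Epochs are baseline
  corrected over [−100, 0) ms; epochs with any |sample| > 100 µV are
  rejected.
* HEP epochs use the first three heartbeats of each trial, movement (VEP)
  epochs the first three movement onsets — both strictly before the
  go-cue, keeping motor activity out of those windows.
* EEG preprocessing: 0.1 Hz high-pass (2nd-order Butterworth, run
  forwards and backwards; an FIR at that edge would need >10⁴ taps),
  40 Hz low-pass (Hamming FIR, zero-phase via two FFT passes), average
  reference. ECG: 1–40 Hz Hamming-window FIR, zero-phase, transition ≈
  1 Hz.
* R-peak detection: local maxima above half the global maximum with a
  250 ms refractory period (larger peak wins). Scale-invariant by
  construction; adequate for synthetic and clean ECG, not for clinical
  noise.

## 6. Cardiac-field-artifact correction

Random triggers are placed uniformly over the cardiac cycles of the period
of interest and classified as systole or diastole by their position in the
cycle; per phase, segments of (−1000, 2000) ms around the triggers are
averaged (baseline: 100 ms pre-trigger). That trigger-locked average is
kept as the phase's artifact estimate. For *subtraction*, however, a
trigger-locked average of an R-locked artifact is smeared by the trigger
offset distribution and cannot cancel it; the estimator therefore also
re-epochs the same classified triggers time-locked to each trigger's
preceding R-peak, and `subtractCfa()` removes that R-locked template at
every R-peak, with each beat's subtraction support clipped to its RR
interval so the trace is corrected exactly once. The correction is applied
identically to all conditions. On artifact-only data this removes
essentially all R-locked mean-square power (the test asserts ≥ 90% for
templates estimated from either phase alone).

## 7. Component removal

Component analysis is exercised on the simulator's *known* mixing: the
component set is the injected template sources (exact spatial patterns)
plus one residual component per channel, so decompose→reconstruct is
lossless by construction and deletion has an analytic truth. A blind PCA
hook is provided for data without ground truth; re-deriving ICA is outside
the package's scope. Components are ranked by magnitude-squared coherence
between component time course and ECG — Welch-averaged spectra
(Hamming-windowed 4-s segments, 50% overlap), averaged over 0.5–10 Hz,
where cardiac quasi-periodicity lives; a scalar-correlation estimator is
available since "coherence" can be read either way. Constant components
have undefined coherence and rank last; top-30 truncation is supported.

## 8. Cluster-based permutation testing

Dependent-samples t at every channel × sample; cells with |t| above the
two-tailed parametric critical value (α_cluster = 0.05, the conventional
cluster-forming default — the procedure itself fixes none) are clustered
by temporal adjacency, spatial adjacency (electrodes within 5 cm on the
montage) and common sign; the cluster statistic is the summed t; the null
is the maximum |summed t| over within-subject condition swaps, i.e. sign
flips of the subject difference maps. With n subjects and 2^n ≤ the
requested permutations the sign assignments are enumerated exhaustively
(exact p); otherwise Monte-Carlo with p = (count ≥ observed + 1)/(N + 1),
which never returns zero. Zero-variance cells get a fixed ±10⁶ sentinel so
observed and permuted maps stay comparable. Degenerate map-wide ties are
resolved with a relative 10⁻⁸ tolerance when comparing permutation maxima
to observed sums (the identity permutation reproduces the observed map
only up to floating-point accumulation order). Cluster labeling is one
C++ routine shared by the observed and permuted paths; the test suite
checks it against an independent brute-force enumeration at 4 subjects and
calibrates the family-wise false-positive rate on 500 null datasets.

## 9. Condition-effect models

ROI amplitudes (mean over ROI channels × window) per subject × condition
are modelled with `lmerTest`: response ~ condition + (1 | subject), the
no-distractor condition as reference (systole for the VEP family, which
has no distractor-free movement events). An ERP amplitude can enter as a
continuous fixed effect with or without its interaction with condition
(for SSD/SSRT models); the main-effects and interaction candidates are
compared by ML AIC and both AICs are reported — selection is not optimised
over. Reported fits use REML for unbiased variance estimates. A singular
fit (zero subject variance) falls back to within-subject paired contrasts,
flagged. We keep a standard intercept with reference coding rather than a
zero-intercept parameterisation: it changes coefficient labels, not the
condition differences the contract (parameter recovery) is about.

## 10. Validation designs and problem sizes

The study-level checks in `tests/testthat/test-acceptance.R` use these
desk-scale designs, chosen as the package's own validation configuration:

* staircase closed loop: 2000 stop trials per condition;
* cluster-test calibration: 500 null datasets of 20 subjects × 8 channels
  × 50 samples at 1000 permutations;
* SSRT recovery: 100 replicates of 1000 go / 500 stop trials;
* end-to-end effect recovery: 50 experiments of 8 subjects, each a
  systole + diastole session of 52 trials per block (12 go / 40 stop —
  stop-heavy so the stop-locked N2 and commission-P3 reach epoch counts
  close to the full design's 50 stop trials per condition), EEG at 125 Hz,
  sensor noise SD 3 µV, 400 permutations per test. The reduced noise is
  the desk-scale counterpart of the full design's trial counts: it gives
  per-subject ERP averages the precision that hundreds of epochs per
  condition would, so the power of the scaled experiment reflects the
  method rather than the shrunken budget. Injected effect sizes are always
  the generator defaults.

## 11. Known limitations

* White, uncorrelated sensor noise; no ocular or muscle artifacts, no
  structured background EEG.
* The race model has no go/stop dependence and no trigger failures;
  SSRT recovery results certify the estimator under the independent-race
  assumption only.
* The T-end rule, CFA template shape and spatial patterns are defensible
  stand-ins, not fitted to measured physiology.
* Phase coding assigns every event to the beat preceding it; events
  before the first recorded R-peak are flagged, not guessed.
* The session container stores signals as text matrices — transparent
  and value-exact, but large for long high-rate recordings.
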