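---
title: "Micro-movement spike trains and the Gamma parameter plane: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-movement spike trains and the Gamma parameter plane: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micromov)
```

## The model

`micromov` treats a continuous biophysical waveform — the angular
acceleration of a pointing hand, the inter-beat intervals of the
heart — as a point process whose events are the waveform's local
peaks. Two fluctuation series are read off that process:

* **Amplitude micro-movements (AM).** Each peak is normalized against
  its own local baseline, `AM = peak / (peak + flank)`, where `flank`
  is the average of all samples from the left flanking minimum to the
  right flanking minimum, inclusive. The ratio is unit-less and lies
  strictly in (0, 1); rescaling the whole waveform by any positive
  constant leaves it unchanged, which removes allometric differences
  (limb size, sensor gain) between participants. Because the peak is
  the maximum of its own window, AM is bounded below by 0.5 under
  this convention; the raw peak amplitudes are carried alongside so
  that the native physical scale is never lost.
* **Timing micro-movements (TM/NTM).** TM is the series of inter-peak
  intervals in seconds; NTM applies the same peak normalization to
  the TM sequence itself.

Pooled over an experimental session (all trials of one condition),
each series is fit by maximum likelihood with the two-parameter Gamma
family, shape `a` and scale `b`. The Gamma family nests the
memoryless Exponential at `a = 1` and approaches the Gaussian as `a`
grows, so a single continuous family spans the regimes of interest.
Two identities organize the interpretation: the noise-to-signal ratio
`var/mean = b` (the scale axis *is* a noise axis), and, whenever a set
of fits shares a common mean `m = a*b`, `log b = log m − log a`, so
the log-log scatter of fitted pairs falls on a line of slope −1 with
intercept `log m`. The package fits that line by ordinary least
squares (`loglog_power_fit()`), natural log by default.

The model's working assumptions: samples are uniformly spaced in
time; the analyzed waveform is a non-negative magnitude (speed,
angular-acceleration magnitude, intervals); peaks pooled within one
condition are exchangeable draws from one stationary law for the
duration of the session; and the sample is large enough (ideally
hundreds of peaks) for asymptotic intervals.

## Estimation

The Gamma MLE solves the profile score
`log(a) − digamma(a) = log(mean(x)) − mean(log(x))` by Newton
iteration from the method-of-moments start `mean(x)^2 / var(x)`,
with `b = mean(x)/a` at the solution. Convergence tolerance is a
relative `1e-10` on the shape with a hard cap of 100 iterations
(non-convergence is an error with diagnostics, not a silent result);
negative Newton steps are halved until the iterate stays positive.
Confidence intervals are Wald intervals on `(log a, log b)` from the
inverse observed Fisher information, back-transformed — the log
parameterization keeps intervals inside the positive quadrant and
makes them asymmetric in the natural direction. The acceptance suite
measures the empirical coverage of the default 95% shape interval at
around 94–95% over 1,000 simulated datasets of 300 draws, i.e. the
slight anti-conservatism of the Wald construction is within the
Monte-Carlo band at that sample size. A minimum of 10 samples is
enforced and fits on fewer than 100 warn, since intervals below that
size are too wide to be useful on these data.

Degenerate inputs are handled explicitly rather than propagated:
constant samples (zero spread) are a hard error for the fitter;
constant samples in the Freedman–Diaconis histogram fall back to two
equal bins with a warning; zero-variance samples are an error for the
normality test; zero-variance paired differences mark the paired
t-test result as degenerate instead of erroring mid-report.

## Peak detection and its conventions

`detect_extrema()` classifies strict sign changes of the first
difference, so maxima and minima alternate by construction. Two
tie-break rules make it deterministic: plateaus contribute their
first sample, and boundary samples are never extrema. The first and
last extrema of a segment lack one flanking minimum; since the AM
normalization is undefined there, those peaks are discarded by
`compute_am()` (a session loses roughly two peaks per movement
segment this way — immaterial once hundreds are pooled). The default
prominence threshold is 0 — every sign change counts, so the raw peak
count is itself usable as a movement-intensity metric — but a positive
`min_prominence` prunes adjacent extrema pairs spanning less than the
threshold, smallest first. Pipelines driven by differentiated signals
should set a small positive prominence (e.g. 1 deg/s² against peak
amplitudes of order 100) because numerical differentiation leaves
sub-unit ripple around zero that would otherwise register as spurious
alternations.

For NTM, mapping a min-to-min *window* onto a *sequence of intervals*
admits more than one reading, and the package implements two, both
scale-invariant. `series_minima` (default) treats the TM sequence as
a discrete signal: each interior TM maximum is normalized by itself
plus the mean of its two flanking minima — for a TM triple (1, 3, 1)
this gives 3/(3+1) = 0.75. Note the flank here is the average of the
two flanking minimum *values*, not of the whole window: between
adjacent TM entries there are no further samples to average, so the
window convention used for AM has no literal counterpart.
`global_mean` normalizes every interval by itself plus the session
mean TM, keeping all intervals instead of only the locally maximal
ones. Neither convention is asserted to be canonical; reports record
which was used.

## ECG branch

The raw ECG is band-passed at 5–30 Hz (the band carrying the QRS
complex) with a 2nd-order Butterworth IIR design, applied forward and
backward. Zero-phase application preserves R-peak *timing* — which
the IBI analysis depends on — at the cost of squaring the magnitude
response (−6 dB rather than −3 dB at the edges for the combined
pass); the single-pass response is what `design_bandpass()`
characterizes and what the tests check at ±0.1 dB. R-peaks are local
maxima above half of a rolling 5-s amplitude envelope, separated by a
250 ms refractory period (a physiological ceiling near 240 bpm), with
polarity auto-corrected when the dominant deflections are negative.
These thresholds are conventions validated on synthetic ECG — clean
recovery is exact, and at 10 dB SNR at least 99% of beats are
recovered within ±2 samples in the test suite — not claims about any
particular recording hardware. Intervals exceeding twice a local
running median (11-interval window, the tested interval excluded so a
dropout cannot mask itself) are flagged as suspected missed beats and
never deleted; `plot_ibi_inspection()` renders the flags for review.
IBIs feed the Gamma platform directly in seconds, without the AM
normalization.

## Kinematics branch

Derivatives are estimated with Savitzky–Golay smoothing
differentiation: window 21 samples (~87 ms at 240 Hz), polynomial
order 3, endpoints fitted one-sided. Both knobs are exposed; the
defaults differentiate polynomials exactly, attenuate a synthetic
acceleration bump train by only ~2% (a purely multiplicative effect,
which the scale-equivariant Gamma fit absorbs), and suppress
white-noise amplification relative to naive differencing. The window
also sets the resolution floor: two peaks closer than about half a
window, or a small peak riding the smoothed shoulder of a much larger
neighbor, merge into one. In generated sessions this costs roughly
one peak in several hundred under the heaviest-load preset.

Each trial is split at the sample minimizing the hand-to-target
distance (the touch, where speed is near zero). Movement onset and
offset use a relative threshold — 5% of the trial's peak speed,
sustained for at least 50 ms — which is robust to unit changes;
"near-zero speed" has no absolute definition across setups. Because
the retraction outlasts the response event, the segmentation window
for a trial runs from its prompt to the next trial's prompt. Segments
are half-open `[start, end)` sample intervals, so forward and
backward partition the movement with no shared or orphaned samples.
The time-estimation error maps the 0–1 slider response to seconds via
a configurable full-scale value (default 1 s); the mapping is a
convention of this implementation.

## What the generator emulates — and what it does not

`simulate_pointing_session()` reproduces the *structure* of a
cognitive-load pointing study: 60 trials per condition at 240 Hz,
forward and backward motions of ~1.5 s each, prompt/touch/tone/
response events with tone delays drawn from {0.1, 0.4, 0.7} s, and a
0–1 slider response in the time-estimation condition. Kinematic
trials use minimum-jerk position profiles (bell-shaped speed, the
distance minimum exactly at the planted touch); the angular-rate
channel integrates a train of Gaussian acceleration bumps (σ = 30 ms)
whose amplitudes are i.i.d. draws from the condition's Gamma law and
whose gaps follow a shifted-Gamma law (shift 0.1 s, which also keeps
adjacent bumps resolvable at the default smoothing). Condition
presets move shape down and NSR up with load (control 3.0/50 →
low 2.2/90 → high 1.6/160 deg/s²) and shorten gaps so loaded trials
carry more peaks; adjacent presets are separated by Kolmogorov
distances of ~0.13–0.28, enough for a 60-trial session to flag the
shift. `simulate_ecg()` renders beats as symmetric
difference-of-Gaussians pulses of ~80 ms support (spectral content
inside the 5–30 Hz band) at Gamma-distributed intervals, plus white
noise at a prescribed SNR and a 0.3 Hz sinusoidal baseline wander.
`make_cohort()` draws per-participant shapes log-uniformly and can
constrain all amplitude means to be equal, which pins the log-log
plane scatter to the slope −1 line and makes that algebraic identity
testable end to end.

The generator is a test fixture, not a biomechanical claim: it has no
multi-joint kinematics, no P/T waves or respiratory coupling in the
ECG, no within-session drift (each condition is stationary by
construction), and its bump train is additive where real angular
acceleration is not. Passing tests therefore demonstrate that the
pipeline recovers known structure through realistic processing
(integration, smoothing, segmentation, detection) — they do not
certify performance on any particular laboratory's recordings.

## Numerical and design choices

* Uniform-sampling tolerance: 1% of the sampling interval; worse
  files are rejected, not resampled, because the differentiators
  assume uniformity. Interior missing samples may be linearly
  interpolated on request and are counted in the validation report;
  boundary missing samples are always an error.
* The Gamma density is evaluated in log space; at `x = 0` it takes
  its analytic limit (`1/b` at `a = 1`, 0 above, `Inf` below).
* IQR for the Freedman–Diaconis rule uses linear-interpolation
  quantiles (R type 7); bins keep the exact FD width, with the final
  bin padded past the maximum.
* KS p-values are asymptotic. The normality test matches the
  normal's mean and SD to the sample, which biases the asymptotic p
  upward (the Lilliefors issue); a Monte-Carlo calibrated p is
  available via `mc_correct = TRUE` rather than silently substituted,
  and for the strongly skewed samples this platform targets either
  version rejects decisively. Pairwise condition tests are reported
  raw and Benjamini–Hochberg adjusted.
* The log-log power fit defaults to natural logarithms (base-10
  selectable) and ordinary — not orthogonal — least squares; both are
  conventions, recorded in the result.
* Model choice is reported, not enforced: `compare_distribution_fits()`
  ranks Gamma, exponential, lognormal and normal by AIC on the same
  sample, but the platform's estimates always come from the Gamma
  family, with the exponential available as the nested `a = 1` case.
* JSON reports embed a schema version, the package version, the seed
  and an MD5 hash of the analysis parameters (filesystem paths
  excluded), so identical analyses of identical inputs are
  byte-identical.

## Problem sizes

The test suite validates at deliberately modest scales: sessions of
1–60 trials, ECG records of 20 s–10 min, cohorts of 9 participants at
30–60 trials, 1,000-replicate coverage simulations of 300 draws each,
and brute-force oracle comparisons on series up to a few hundred
samples. The full suite and the acceptance script each run in well
under a minute on a single CPU; all sizes are package choices made to
keep the feedback loop fast while leaving every statistical check
adequately powered.

## Known limitations

Wald intervals are mildly anti-conservative below ~100 samples (hence
the warning); the smoothing window bounds peak resolvability as
described above; orientation math starts from a provided angular-rate
channel (quaternion reconstruction is out of scope); the ECG branch
does not delineate Q/S/T morphology or compute frequency-domain HRV;
and Gamma estimation is single-window per condition — streaming or
windowed estimation over long recordings is not implemented.
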