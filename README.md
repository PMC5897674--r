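# micromov

Micro-movement spike trains and Gamma-process signatures for
biophysical time series.

## The problem

Conventional analyses of movement and heart data average trials and
assume normality, discarding the moment-by-moment fluctuations that
carry most of the information about an individual nervous system.
`micromov` implements the opposite program: it converts continuous
biophysical waveforms — hand kinematics sampled at ~240 Hz,
electrocardiograms at ~256 Hz — into *spike trains* of normalized peak
fluctuations and estimates a **personalized empirical probability
distribution** for each participant and condition, instead of fitting
one grand mean to everyone. It is aimed at researchers in motor
control, embodied cognition and psychophysiology who record continuous
kinematic or autonomic signals and want distribution-level, per-person
statistics.

## The core statistic

Every local peak of a non-negative magnitude waveform (angular
acceleration, speed, inter-beat intervals) is normalized against its
local baseline,

    AM_i = peak_i / (peak_i + avg(min-to-min window around peak_i)),

yielding unit-less *amplitude micro-movements* in (0, 1); the
inter-peak intervals (TM) and their normalized counterpart (NTM) carry
the timing fluctuations. Pooled over a session, these samples are fit
by maximum likelihood with the two-parameter Gamma family

    f(x | a, b) = 1 / (Gamma(a) b^a) * x^(a-1) * exp(-x/b),

with Wald confidence intervals from the observed Fisher information on
(log a, log b). The fitted pair (a, b) is one point on the **Gamma
parameter plane**: shape a = 1 marks the memoryless Exponential
boundary, and the scale b equals the noise-to-signal ratio exactly,
since

    NSR = var/mean = (a b^2)/(a b) = b.

Across participants with similar micro-movement means the plane
scatter collapses onto a log-log line of slope −1 (because
log b = log mean − log a), which the package fits; shifts along and
off that line, tested pairwise with Kolmogorov–Smirnov statistics,
track how cognitive load or task context reshapes each person's
stochastic signature. The ECG branch band-passes the signal with a
5–30 Hz 2nd-order Butterworth filter (applied bidirectionally, so
R-peak times are phase-true), detects R-peaks, and feeds the
inter-beat intervals to the same Gamma platform.

Because no recordings ship with the package, a ground-truthed
synthetic-data module generates study-sized sessions (60 pointing
trials per condition, ~1.5 s forward and backward motions, planted
Gamma-distributed peak amplitudes, QRS-like ECG with Gamma-distributed
inter-beat intervals) so that every pipeline stage can be validated
end to end against known truth.

## Worked example

```r
library(micromov)

# one participant, 60 pointing trials under each of two cognitive loads
low  <- simulate_pointing_session("P01", "low_load",  n_trials = 60, seed = 31)
high <- simulate_pointing_session("P01", "high_load", n_trials = 60, seed = 32)

# segment every trial, detect angular-acceleration peaks, normalize
ex_low  <- extract_session(low$session,  min_prominence = 1)
ex_high <- extract_session(high$session, min_prominence = 1)

# personalized Gamma signature: raw peak amplitudes pooled over the session
amps_low  <- c(ex_low$am$forward$raw_values,  ex_low$am$backward$raw_values)
amps_high <- c(ex_high$am$forward$raw_values, ex_high$am$backward$raw_values)
fit_low <- fit_gamma_mle(amps_low)
print(fit_low)

rep <- condition_shift_report(list(low_load = amps_low, high_load = amps_high))
print(rep$pairwise, row.names = FALSE)
```

prints

```
Gamma MLE fit (raw, n = 527)
  shape a = 2.239  [2, 2.506] (95% CI)
  scale b = 83.89  [73.92, 95.2]
  NSR (= b) = 83.89, log-likelihood = -3207

   cond_a    cond_b         D            p        p_adj
 low_load high_load 0.1740674 8.456915e-09 8.456915e-09
```

The fit recovers the planted generating law (shape 2.2, scale 90)
within its 95% confidence interval: this participant's low-load
signature sits at shape ≈ 2.2 (right-skewed, far from the Exponential
boundary) with a noise-to-signal ratio of ≈ 84 deg/s². The pairwise
Kolmogorov–Smirnov test flags the shift to the high-load condition
decisively (D = 0.17, p ≈ 1e-8): under load the distribution moves
toward lower shape (more skew) and higher NSR, the direction the
platform is designed to resolve. `plot_gamma_plane()` and
`plot_moments_scatter()` render these shifts as confidence-crosshair
markers on the shape–scale plane and as a kurtosis-sized,
median-colored moments scatter.

A command-line wrapper covering simulation, ECG processing, fitting,
comparison and full pipeline runs ships in `inst/cli/micromov.R`
(`Rscript inst/cli/micromov.R simulate --what ecg --seed 4 --out dir`).

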