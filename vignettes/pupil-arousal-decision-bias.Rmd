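---
title: "Phasic arousal and decision bias: models, generator, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasic arousal and decision bias: models, generator, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilddm)
```

## The scientific problem

Perceptual and memory-based yes/no decisions are biased: observers favor
one response over the other beyond what the evidence warrants. Rapid,
trial-to-trial fluctuations in brain arousal — readable non-invasively from
the pupil — appear to modulate this bias. `pupilddm` packages the full
analysis chain needed to study that relationship: extracting a per-trial
phasic-arousal scalar from pupil traces, binning behavior by that scalar,
quantifying bias with signal-detection theory (SDT) and with the drift
diffusion model (DDM), and running the simulation experiments that
distinguish *which* model parameter carries the arousal effect.

Because raw eye-tracking datasets are large and subject-specific, the
package is built around a synthetic-data generator with a known
ground-truth coupling between latent arousal and drift bias. Every
downstream stage is therefore testable against known truth, and all
claims in the test suite are claims about computations the package itself
performs.

## The behavioral models

### Signal-detection metrics

For each arousal bin we compute sensitivity `d' = z(HR) − z(FAR)` and
criterion `c = −(z(HR) + z(FAR))/2` (positive = conservative). Rates are
corrected by the log-linear rule (+0.5 per cell) so that floor/ceiling
rates remain finite; the package's empirical rates are typically
interior, where the correction is negligible.

In a go/no-go task with randomly interleaved signal loudnesses the
observer can hold only one decision criterion. Per-loudness criteria are
then not comparable, so an overall bias statistic is built from one
standard-normal noise distribution and a *composite* signal distribution:
the average of unit-variance normals centered at each loudness's
empirical d'. The zero-bias point `Z` is the evidence value where the two
densities cross; the choice point is `C = 0.5 d'_i + c_i`, which is the
same constant for every loudness when all criteria derive from the shared
false-alarm rate (this is checked to 10^-9 and violating inputs are
rejected); overall bias is `C − Z`. With one loudness the statistic
reduces exactly to `c`. The crossing is located by scanning
`[min(d)/2 − 3, max(d)/2 + 3]` for sign changes and bisecting to 10^-8;
if several crossings exist the one nearest `mean(d)/2` is used. Mixtures
whose components all have `d' ≤ 0` have no meaningful crossing and raise
an error rather than extrapolate.

### Drift diffusion model

Evidence accumulates from `z_rel · a` toward bounds at `0` and `a` with
per-trial drift `v(stimulus) + v_bias`, within-trial noise `s = 1` (the
common toolbox convention; configurable), across-trial drift variability
`sv`, and non-decision time `t0`. Optional urgency collapses the bounds
hyperbolically, `a_up(t) = clamp(a − a·t/(t+τ), a/2, a)` and mirrored
below, so the bounds meet at `a/2` exactly at `t = τ` and undecided
accumulators are forced to the nearer side (exact ties are randomized
with the seeded RNG).

Two bias mechanisms are distinguishable from RT distributions: a
starting-point shift loads on fast responses (visible in the fastest bin
of the conditional response function), whereas a drift bias shifts
choices across the whole RT range. A third mechanism, bin-varying
urgency combined with a starting-point bias, is included in the model
comparison; collapsing bounds alone produce almost no choice-bias
variation, which is the heart of the three-model experiment below.

### Fitting

Per-subject fitting uses RT-quantile bin counts (quantiles 0.1, 0.3,
0.5, 0.7, 0.9 → six bins per choice; go/no-go uses the yes bins plus a
single no-go count, and noise-only trials form one shared cell) and
minimizes `G² = 2 Σ O log(O / (N p))` by multi-start Nelder–Mead (five
restarts by default, jittered on the transformed scale, followed by a
polish run). Expected bin probabilities come from the analytic Wiener
first-passage density — a series solution switched between its small-time
and large-time forms, integrated on a 1 ms grid — with 7-node
Gauss–Hermite quadrature over `sv`. When bounds collapse no series
solution applies and expected proportions are simulated with common
random numbers (fixed per-cell seeds), keeping the objective smooth
across optimizer iterations. Model comparison uses `BIC = G² + k log n`,
treating G² as the deviance surrogate; differences below 2 are reported
as ties.

Parameters are transformed to unconstrained scales (log for `a` and
`sv`; scaled logistic for `t0` bounded by the fastest observed RT and for
`τ` bounded by twice the slowest observed RT — a later collapse is
observationally equivalent). The noise convention, restart count and
quantile set are arguments.

## The synthetic-data generator

The generator encodes the study designs it emulates:

* **Go/no-go**: mini-blocks of 2–7 one-second trials (0.5 s gaps), the
  unique signal always on the final trial; the first trial of each block
  is a cue and never carries the signal. Block lengths follow a
  truncated-geometric distribution on {2..7} (`p = 0.25`), so the
  marginal probability that the signal falls at position `k` declines
  with `k`. (With finite support the *hazard* at the last position is
  necessarily 1; the declining quantity is the marginal position
  probability.) Signal loudness is balanced within chunks of 60
  mini-blocks. The default human session is exactly 660 trials; mouse
  sessions draw a target uniformly in 2469–3479 trials and use six
  loudness levels.
* **Yes/no and recognition**: stratified signal flags with exact counts
  per 120-trial block (probability 0.5, or 0.3/0.7 for biased
  environments; recognition uses a 50/50 old/new split over 300 trials).
  Yes/no trials are separated by a 3–4 s baseline interval, modeled as a
  3.5 s gap.

**Arousal coupling.** Latent arousal is lognormal with unit median
(`sdlog` 0.5). The effective drift bias on trial `t` is
`bias_base × (1 − γ · ã_t)` with `ã_t` the arousal rank normalized to
[0, 1]. The multiplicative law was chosen because the empirical
phenomenon is suppression of bias of *either* sign toward neutral, which
an additive (liberalizing) law cannot reproduce; the law is configurable
(`coupling_law = "additive"` exists for sensitivity analyses), and the
generative relation is a modeling choice — the analyses only estimate
its consequences. `γ > 1` would flip the bias sign; such trials are
clamped at the configured cap with a warning.

**Pupil traces** are built as
`baseline drift + Σ arousal_t · IRF(t − onset_t) + motor transient ·
IRF(t − response_t) + noise`, sampled at 100 Hz by default (a desk-scale
rate; the decimation stage is separately tested with 1000 Hz input).
The impulse response is the standard pupillometry gamma-family kernel
`h(t) = (t/t_max)^w e^{−w(t/t_max−1)}` with `t_max = 0.93` s and
`w = 10.1`. Baseline wander is white noise smoothed with a 10 s moving
average (amplitude 3% signal change); blinks arrive at 0.1 Hz, blank
100–400 ms of samples (overlapping gaps merged), and leave a small
blink-evoked dilation behind for the deconvolution stage to remove.
The motor transient (response-locked, go/yes only) is causal, so an
early stimulus-locked extraction window escapes it except for the slight
backward smearing introduced by zero-phase filtering.

What the generator does *not* emulate: gaze-dependent foreshortening,
saccadic artifacts, slow oculomotor fatigue, reward/timeout feedback
dynamics, and any learning across the session. Passing tests therefore
certify the pipeline's internal consistency, not its robustness to every
artifact of real recordings.

## Preprocessing

The chain follows the standard published recipe: (i) linear
interpolation across missing-data gaps extended 150 ms on both sides
(edge gaps hold the nearest valid value; a session > 40% missing is
flagged); (ii) zero-phase third-order Butterworth low-pass at 6 Hz;
(iii) for human-style traces, FIR deconvolution of blink- and
saccade-evoked responses on a 6 s epoch anchored at the event offset,
estimated by sparse least squares with an intercept column, and
subtraction of the fitted event-locked contributions; (iv) conversion to
percent signal change about the session mean; (v) decimation to 50 Hz
behind an anti-aliasing low-pass. The derivative is the adjacent-sample
difference scaled to %/s (units matter only up to rank for percentile
binning) and low-passed at 2 Hz.

The phasic-arousal scalar is the 95th percentile of the derivative in a
window of 0.23–0.50 s after trial onset (human go/no-go), 0.04–0.23 s
(mouse), or the 500 ms before the button press (yes/no, choice-locked).
Go responses faster than the window end + 50 ms (0.55 s human, 0.28 s
mouse) are excluded, as are mini-block cue trials; no-go trials are
always retained. Included trials are ranked within stratum (loudness for
go/no-go; noise trials form their own stratum) and split into
equal-population bins — five by default, three for biased yes/no
environments, two for recognition — with ties keeping original order.
The percentile is taken on the 50 Hz (post-decimation) derivative.

Zero-phase (forward–backward) filtering was chosen because the scalar
competes ranks within a session: any phase lag common to all trials is
harmless, but a causal filter's group delay would shift windows relative
to events. Padding uses odd reflection to suppress filter edge
transients.

## Simulator numerics

The simulator integrates the diffusion by Euler–Maruyama at `dt = 1` ms
(2 ms ceiling enforced) with two refinements that make first-passage
statistics accurate at that step: a Brownian-bridge correction that
terminates excursions crossing a bound *within* a step (probability
`exp(−2(b−x)(b−x')/(s²dt))` per side), and crossing-time interpolation
(linear for direct crossings, mid-step for bridge-detected ones).
Without these, the fastest RT bin is deficient by ~2·10⁻³ at 1 ms and
quantile fits absorb the mismatch into spurious drift-rate variability.
With them, simulated defective CDFs agree with the analytic solution to
~4·10⁻⁴ at one million trials, and halving `dt` moves choice fractions
by well under 0.005. Constant-bound paths are censored at a configurable
20 s horizon and flagged.

## The simulation experiments

**Variability confound.** Two conditions share `v = 1`, `a = 1`,
`t0 = 0.3`, `sv = 0` and differ only in drift bias (−0.5 vs 0). Fitting
with condition-varying drift bias recovers the biases and non-decision
time tightly and drift-rate variability near zero; forcing one shared
bias absorbs the untracked difference into apparent `sv`, which grows
monotonically over a disparity grid {0, 0.25, 0.5, 0.75, 1}. The package
runs this at 100K trials per condition and 10 replicates (a desk-scale
stand-in for the original million-trial experiment; `n_trials` restores
any scale). One caveat discovered by the estimator analysis and encoded
in the tests: near `sv = 0` the quantile summary's information about
`sv` is second-order, so the per-replicate MLE is a boundary estimator
scattering over [0, ~0.25] even for exactly distributed data; the
replicate median is asserted to stay below 0.15 and far below the
misspecified model's apparent variability, rather than at an
unattainably tight bound.

**Three-model comparison.** On data generated with bin-varying drift
bias, three equal-complexity fits (bin-varying starting point;
bin-varying drift bias; bin-varying urgency plus a bin-invariant
starting point — a fixed drift bias with varying urgency cannot produce
biases of the observed size) are each forward-simulated at 100K trials
per bin, and per-bin predicted bias/RT/d' are compared to the empirical
values by sum-of-squares residuals. The drift-bias model attains the
smallest residual and the urgency model's predicted bias variation is a
few percent of the generated variation. The urgency model carries one
extra parameter (the shared starting point); BIC penalizes it
accordingly.

**Recovery suite.** Simulate-and-refit tables over a small grid,
including the go/no-go configuration with *both* bias parameters free
per bin, which demonstrates the trade-off (inflated bias RMSE) that
motivates fixing the starting point in go/no-go fits.

## Group statistics

Per-bin metrics are modeled with a nested ladder of linear mixed models
(`lme4`): constant, `+P`, `+P²`, with `S` (loudness) included for
go/no-go; random effects use the maximal structure justified by the
design (by-subject intercepts and `S`/`P` slopes), falling back to
random intercepts when the maximal fit fails. Each higher order is
accepted only if it lowers BIC relative to the current winner (so a
purely quadratic profile is still reachable), and the winner is refitted
by REML. The quadratic term enters as a fixed effect only; a by-subject
quadratic slope is rarely estimable at 2–5 bins per subject.

Time courses are tested with a one-sample cluster permutation test:
pointwise t against zero, clusters of contiguous same-sign
supra-threshold samples, cluster mass = summed t, null distribution from
whole-subject sign flips (10,000 by default; the calibration simulation
uses 400 to keep runtime sane and confirms a familywise error near the
nominal 5%). Pairwise questions use paired t-tests and Pearson
correlations with percentile-bootstrap intervals (60% by default, the
convention for individual-differences scatter plots).

## Problem sizes used by the checks

The shipped tests run the confound experiment at 100K trials per
condition × 10 replicates, the three-model comparison on 3 bins × 8000
trials with 100K-trial forward predictions, the cluster-test calibration
at 1000 replicates × 400 permutations, and the end-to-end pipeline on 12
subjects × 600 yes/no trials at 100 Hz. These sizes were chosen so the
full suite completes on a single CPU while leaving every qualitative
contrast (model ranking, monotonicity, calibration bands) far from its
decision boundary.

## Known limitations

* Per-subject quantile G-square fitting replaces hierarchical Bayesian
  estimation; there is no shrinkage across subjects and no posterior
  uncertainty, so small-n yes/no fits with many bin-varying parameters
  can be ill-posed — the freeze flags (`fit_z`, `fit_vbias`, `fit_sv`)
  exist for exactly that reason.
* Only drift-rate variability is modeled across trials (no
  starting-point or non-decision-time variability).
* The arousal→bias coupling law in the generator is an assumption, made
  configurable; real data constrain only its estimated consequences.
* The composite-bias statistic requires at least one positive-d'
  component and a crossing in the scanned range; degenerate bins (tiny
  trial counts) are dropped by the pipeline with their subjects' other
  bins retained.
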