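# pupilddm

Phasic arousal — the moment-to-moment state of neuromodulatory brainstem
systems, read out non-invasively from the pupil — predicts *how biased* a
decision-maker is from one trial to the next. `pupilddm` is an R package
for researchers in computational cognitive neuroscience and
pupillometry who want to quantify that relationship and, crucially, to
identify *which* computational parameter carries it. It implements the
full analysis chain on top of a synthetic-data generator with known
ground truth, so every stage is testable without any eye-tracker data.

## What the package computes

**Signal-detection metrics per arousal bin.** Sensitivity
`d′ = z(HR) − z(FAR)` and criterion `c = −(z(HR) + z(FAR))/2`, plus a
composite-distribution *overall bias* for go/no-go tasks where one
decision criterion serves several signal loudnesses: with a standard
normal noise distribution `N` and a composite signal distribution `S`
(the average of unit-variance normals centered at each loudness's `d′`),
the zero-bias point `Z` solves `S(Z) − N(Z) = 0`, the choice point is
`C = 0.5·d′ᵢ + cᵢ` (identical across loudnesses sharing one false-alarm
rate), and overall bias is `C − Z`.

**Drift diffusion modeling.** Noisy evidence accumulates from `z·a`
toward bounds `0` and `a` with drift `v + v_bias`, across-trial drift
variability `sv`, non-decision time `t0`, and optionally hyperbolically
collapsing bounds `a_up(t) = clamp(a − a·t/(t+τ), a/2, a)` (urgency).
The simulator is bridge-corrected Euler–Maruyama; fitting minimizes the
RT-quantile G-square statistic
`G² = 2 Σ Oᵢ ln(Oᵢ / (N pᵢ))` over bins built from the 0.1/0.3/0.5/0.7/0.9
quantiles (plus a single no-go count for go/no-go data), with expected
proportions from the analytic Wiener first-passage solution (or
common-random-number simulation under collapsing bounds). Model
selection uses `BIC = G² + k ln n`.

**Pupil preprocessing.** Blink interpolation, zero-phase Butterworth
filtering, FIR deconvolution of blink/saccade responses, percent-signal
change conversion, 50 Hz decimation, derivative computation, per-trial
phasic scalars (95th percentile of the derivative in task-specific
windows), fast-RT exclusions and equal-population arousal binning.

**Simulation experiments.** The drift-rate-variability confound
(untracked condition differences in drift bias masquerade as `sv`), the
three-way equal-complexity comparison of starting-point vs drift-bias vs
urgency mechanisms with sum-of-squares residuals, and parameter-recovery
tables including the go/no-go two-bias non-identifiability.

**Group statistics.** Sequential polynomial mixed-model selection
(constant → linear → quadratic in arousal bin, BIC-guided, REML refit),
cluster-corrected one-sample permutation tests on time courses, paired
t-tests, and bootstrap Pearson correlations.

## Worked example

Simulate a 12-subject yes/no cohort whose drift bias is suppressed
toward zero on high-arousal trials (`coupling_gamma = 1`, conservative
baseline bias −0.5), run the full pipeline (trace synthesis →
preprocessing → binning → SDT → group model selection):

```r
library(pupilddm)

cfg <- pipeline_config(
  task = task_spec("yesno", n_subjects = 12, trials_per_subject = 600,
                   sampling_rate_hz = 100),
  coupling = arousal_coupling_spec(coupling_gamma = 1),
  bias_base = -0.5, seed = 21)
res <- run_pipeline(cfg)
print(res)
print(res$group_fit)
```

```
Pupil-arousal decision-bias pipeline
  12 subjects, 7200 analyzed trials, task yesno
  group-mean bias by arousal bin:
  bin0   bin1   bin2   bin3   bin4
0.2867 0.1984 0.2393 0.1123 0.0505
  selected pupil dependence: linear
Sequential polynomial mixed-model selection
  selected order: linear
  BIC: constant=-37.4  linear=-46.1  quadratic=-42.7
            Estimate Std. Error t value
(Intercept)   0.2891     0.0355  8.1445
P            -0.0559     0.0125 -4.4612
```

The group-mean criterion declines from 0.29 (conservative) in the lowest
arousal bin to 0.05 (near neutral) in the highest; the sequential
mixed-model analysis selects a first-order (linear) dependence on
arousal bin with slope −0.056 z-units per bin. Rerunning with
`coupling_gamma = 0` selects the constant model — no spurious arousal
effect. `render_report(res)` produces the per-bin figures with the
selected polynomial overlay.

## Package layout

- `R/synthetic-*.R` — task designs, arousal-coupled behavior, pupil
  trace synthesis, dataset writer.
- `R/preproc*.R` — trace cleaning, deconvolution, normalization,
  derivative, scalars, exclusions, binning.
- `R/sdt.R` — d′/criterion and the composite overall-bias statistic.
- `R/ddm-*.R`, `src/ddm.cpp` — simulator, first-passage machinery,
  quantile G-square fitter, model comparison.
- `R/experiments.R` — confound, three-model and recovery experiments.
- `R/group-stats.R` — mixed models, cluster permutation, associations.
- `R/pipeline.R` — end-to-end orchestration and reporting.
- `vignettes/pupil-arousal-decision-bias.Rmd` — the methods vignette:
  models, generator assumptions, numerical choices, limitations.
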