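# small trace builders used across the preprocessing tests
flat_trace <- function(n = 2000, fs = 100, value = 100) {
  pupil_trace(rep(value, n), fs)
}

test_that("gap interpolation bridges gaps and holds edges", {
  fs <- 100
  x <- rep(1, 500)
  miss <- rep(FALSE, 500)
  x[200:230] <- NA; miss[200:230] <- TRUE
  tr <- pupil_trace(x, fs, missing = miss)
  cfg <- preproc_config()
  out <- clean_trace(tr, cfg)
  expect_false(any(out$missing))
  expect_true(all(abs(out$samples - 1) < 1e-6))  # equal anchors: filled flat

  # ramp anchors: linear bridge between padded anchors
  x2 <- c(rep(1, 250), rep(2, 250))
  miss2 <- rep(FALSE, 500); miss2[240:260] <- TRUE
  x2[240:260] <- NA
  out2 <- clean_trace(pupil_trace(x2, fs, missing = miss2), cfg)
  mid <- out2$samples[250]
  expect_gt(mid, 1.2); expect_lt(mid, 1.8)
  expect_true(all(diff(out2$samples[235:265]) >= -1e-9))

  # gap at the trace edge is held at the nearest valid value
  x3 <- rep(5, 300); x3[1:20] <- NA
  out3 <- clean_trace(pupil_trace(x3, fs,
                                  missing = c(rep(TRUE, 20),
                                              rep(FALSE, 280))), cfg)
  expect_true(all(abs(out3$samples - 5) < 1e-6))
  expect_error(clean_trace(pupil_trace(rep(NA_real_, 100), fs,
                                       missing = rep(TRUE, 100)), cfg),
               "fully missing")
})

test_that("cleaning is idempotent", {
  set.seed(31)
  x <- 100 + cumsum(rnorm(3000, sd = 0.05))
  miss <- rep(FALSE, 3000); miss[1000:1040] <- TRUE
  tr <- pupil_trace(x, 100, missing = miss)
  once <- clean_trace(tr)
  expect_false(any(once$missing))
  twice <- clean_trace(once)
  # no gaps remain, and re-filtering already band-limited content is a
  # near-identity
  expect_false(any(twice$missing))
  expect_lt(max(abs(twice$samples - once$samples)), 0.03)
  expect_gt(cor(twice$samples, once$samples), 0.9999)
})

test_that("low-pass stage matches the squared Butterworth magnitude", {
  fs <- 100
  t <- seq(0, 20, by = 1 / fs)
  f_test <- 10
  x <- sin(2 * pi * f_test * t)
  tr <- pupil_trace(100 + x, fs)
  out <- clean_trace(tr, preproc_config())
  # steady-state amplitude away from the edges
  mid <- out$samples[500:1500] - mean(out$samples[500:1500])
  amp <- sqrt(2 * mean(mid^2))
  # zero-phase = forward + backward: squared magnitude of the digital
  # (bilinear-transformed) third-order Butterworth at f/fc
  warp <- tan(pi * f_test / fs) / tan(pi * 6 / fs)
  gain <- 1 / (1 + warp^6)
  expect_equal(amp, gain, tolerance = 0.05 * gain + 0.005)
})

test_that("deconvolution recovers an injected blink response", {
  fs <- 50
  n <- fs * 200
  set.seed(32)
  blink_t <- sort(runif(40, 5, 190))
  irf <- pupil_irf(seq(0, 4, by = 1 / fs), tmax = 1, shape = 6)
  x <- rep(100, n)
  for (bt in blink_t) {
    i0 <- round(bt * fs) + 1
    span <- i0:min(n, i0 + length(irf) - 1)
    x[span] <- x[span] + 2 * irf[seq_along(span)]
  }
  tr <- pupil_trace(x, fs,
                    events = data.frame(kind = "blink", time_s = blink_t))
  cfg <- preproc_config(deconv_epoch_s = 5)
  out <- deconvolve_artifacts(tr, cfg)
  # residual trace is flat again
  expect_lt(sd(out$samples), 0.05)
  fir <- attr(out, "fir")$blink
  expect_equal(max(fir), 2, tolerance = 0.1)
  # no events: identity
  tr0 <- pupil_trace(x, fs)
  expect_identical(deconvolve_artifacts(tr0, cfg)$samples, x)
  # one event: warn and skip
  tr1 <- pupil_trace(x, fs, events = data.frame(kind = "blink",
                                                time_s = 5))
  expect_warning(deconvolve_artifacts(tr1, cfg), "too few events")
})

test_that("normalization gives percent signal change and exact decimation", {
  expect_true(all(normalize_downsample(flat_trace(),
                                       preproc_config())$samples == 0))
  n <- 100000
  tr <- pupil_trace(100 + sin(seq_len(n) / 5000), 1000)
  out <- normalize_downsample(tr, preproc_config())
  expect_equal(length(out$samples), n / 20)   # 1000 Hz -> 50 Hz
  expect_equal(out$rate_hz, 50)
  expect_lt(abs(mean(out$samples)), 0.05)
  expect_error(normalize_downsample(pupil_trace(rep(-5, 100), 100),
                                    preproc_config()), "positive")
})

test_that("derivative matches calculus oracles", {
  fs <- 50
  cfg <- preproc_config()
  # linear trace of slope m %/s
  m <- 3
  tr <- pupil_trace(m * (seq_len(1000) - 1) / fs, fs)
  d <- compute_derivative(tr, cfg)
  expect_true(all(abs(d$samples[100:900] - m) < 0.01))
  # constant: zero
  d0 <- compute_derivative(pupil_trace(rep(2, 500), fs), cfg)
  expect_true(all(abs(d0$samples) < 1e-9))
  # slow sinusoid: amplitude 2 pi f A
  f <- 0.3; A <- 2
  t <- (seq_len(5000) - 1) / fs
  ds <- compute_derivative(pupil_trace(A * sin(2 * pi * f * t), fs), cfg)
  ampl <- max(ds$samples[1000:4000])
  expect_equal(ampl, 2 * pi * f * A, tolerance = 0.05)
  expect_error(compute_derivative(pupil_trace(rep(1, 10), fs), cfg),
               "shorter")
})

test_that("phasic scalar is the window percentile of the derivative", {
  fs <- 50
  cfg <- preproc_config(species = "human", task_kind = "gonogo")
  expect_equal(cfg$scalar_window$start_s, 0.23)
  expect_equal(cfg$scalar_window$end_s, 0.50)
  expect_equal(preproc_config("mouse", "gonogo")$scalar_window$start_s,
               0.04)
  n <- 500
  const <- pupil_trace(rep(1.7, n), fs,
                       events = data.frame(kind = "trial_onset",
                                           time_s = 3))
  trials <- data.frame(rt_s = NA_real_, choice = 0L)
  out <- extract_phasic_scalar(const, const, trials, cfg)
  expect_equal(out$phasic_scalar, 1.7)

  # linear 0 -> 1 derivative across the window: 95th percentile = 0.95
  i0 <- as.integer(ceiling((3 + 0.23) * fs - 1e-6)) + 1L
  i1 <- as.integer(floor((3 + 0.50) * fs + 1e-6)) + 1L
  x <- numeric(n)
  x[i0:i1] <- seq(0, 1, length.out = i1 - i0 + 1)
  dtr <- pupil_trace(x, fs, events = data.frame(kind = "trial_onset",
                                                time_s = 3))
  out2 <- extract_phasic_scalar(dtr, dtr, trials, cfg)
  expect_equal(out2$phasic_scalar, 0.95, tolerance = 0.005)
})

test_that("fast-RT and cue exclusions follow the window-plus-buffer rule", {
  cfg <- preproc_config(species = "human", task_kind = "gonogo")
  expect_equal(cfg$rt_cutoff_s, 0.55)
  trials <- data.frame(choice = c(1L, 1L, 1L, 0L, 1L),
                       rt_s = c(0.20, 0.30, 0.60, NA, 0.56),
                       is_cue_trial = c(0L, 0L, 0L, 0L, 1L))
  kept <- exclude_fast_trials(trials, cfg)
  expect_equal(kept$rt_s[kept$choice == 1], 0.60)  # fast go + cue dropped
  expect_equal(nrow(kept), 2)                      # no-go retained
  slow <- data.frame(choice = 1L, rt_s = c(0.9, 1.2),
                     is_cue_trial = 0L)
  expect_equal(nrow(exclude_fast_trials(slow, cfg)), 2)
})

test_that("arousal bins are equal-population within strata", {
  cfg <- preproc_config(n_bins = 5)
  tr <- data.frame(phasic_scalar = rnorm(100), included = TRUE)
  out <- assign_pupil_bins(tr, cfg)
  expect_true(all(table(out$pupil_bin) == 20))

  tr2 <- data.frame(phasic_scalar = rnorm(500),
                    loudness_db = rep(c(-20, -10), each = 250),
                    included = TRUE)
  out2 <- assign_pupil_bins(tr2, cfg, stratify_by = "loudness_db")
  tab <- table(out2$pupil_bin, out2$loudness_db)
  expect_true(all(tab == 50))
  # bins ordered by scalar within stratum
  m <- tapply(out2$phasic_scalar, out2$pupil_bin, mean)
  expect_true(all(diff(m) > 0))
  # populations never differ by more than one
  tr3 <- data.frame(phasic_scalar = rnorm(103), included = TRUE)
  tab3 <- table(assign_pupil_bins(tr3, cfg)$pupil_bin)
  expect_lte(diff(range(tab3)), 1)
  expect_warning(assign_pupil_bins(
    data.frame(phasic_scalar = rnorm(3), included = TRUE), cfg),
    "fewer trials than bins")
})
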