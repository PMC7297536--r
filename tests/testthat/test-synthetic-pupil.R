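mini_session <- function(n_trials = 40, gamma = 1, noise_sd = 0.5,
                         blink_rate = 0.1, motor = 2, seed = 1,
                         arousal_sdlog = 0.5) {
  spec <- task_spec("yesno", trials_per_subject = n_trials,
                    sampling_rate_hz = 100)
  design <- make_yesno_design(spec, seed = seed)
  coup <- arousal_coupling_spec(coupling_gamma = gamma,
                                noise_sd = noise_sd,
                                blink_rate_hz = blink_rate,
                                motor_transient_amp = motor,
                                arousal_sdlog = arousal_sdlog)
  params <- ddm_params(v = 1, v_bias = -0.3, a = 1, t0 = 0.4)
  beh <- simulate_subject_behavior(design, params, coup, seed = seed,
                                   task = "yesno")
  trace <- synthesize_pupil_traces(design, beh$truth, beh$trials, coup,
                                   spec, seed = seed)
  list(spec = spec, design = design, coup = coup, beh = beh,
       trace = trace)
}

test_that("noiseless constant-arousal traces have identical trial epochs", {
  spec <- task_spec("yesno", trials_per_subject = 20,
                    sampling_rate_hz = 100)
  design <- make_yesno_design(spec, seed = 2)
  coup <- arousal_coupling_spec(coupling_gamma = 0, noise_sd = 0,
                                blink_rate_hz = 0,
                                motor_transient_amp = 0,
                                baseline_drift_amp = 0,
                                arousal_sdlog = 0)
  params <- ddm_params(v = 1, v_bias = 0, a = 1, t0 = 0.4)
  beh <- simulate_subject_behavior(design, params, coup, seed = 2,
                                   task = "yesno")
  trace <- synthesize_pupil_traces(design, beh$truth, beh$trials, coup,
                                   spec, seed = 2)
  onsets <- trace$events$time_s[trace$events$kind == "trial_onset"]
  fs <- trace$rate_hz
  # skip the first epochs, whose predecessors' response tails are still
  # settling; from the fourth trial every epoch sees identical history
  epochs <- vapply(onsets[4:15], function(o) {
    i0 <- round(o * fs) + 1
    trace$samples[i0:(i0 + fs - 1)]
  }, numeric(fs))
  spread <- apply(epochs, 1, function(r) diff(range(r)))
  expect_lt(max(spread), 1e-9)
  expect_false(any(trace$missing))
})

test_that("traces are reproducible and blink gaps are well-formed", {
  s1 <- mini_session(seed = 3)
  s2 <- mini_session(seed = 3)
  expect_identical(s1$trace$samples, s2$trace$samples)
  expect_identical(s1$trace$missing, s2$trace$missing)
  # gaps (ignoring edges) are bounded and non-degenerate after merging
  r <- rle(s1$trace$missing)
  gaps <- r$lengths[r$values]
  expect_true(all(gaps > 0))
  blinks <- s1$trace$events$time_s[s1$trace$events$kind == "blink"]
  expect_true(!is.unsorted(blinks))
})

test_that("phasic scalar recovers latent arousal through the full pipeline", {
  # low-noise setting: slow baseline wander is the dominant nuisance for
  # a derivative-based scalar, so it is reduced along with sensor noise
  s <- mini_session(n_trials = 120, noise_sd = 0.02, blink_rate = 0.05,
                    seed = 4)
  s$coup$baseline_drift_amp <- 1
  s$trace <- synthesize_pupil_traces(s$design, s$beh$truth,
                                     s$beh$trials, s$coup, s$spec,
                                     seed = 4)
  cfg <- preproc_config(species = "human", task_kind = "yesno")
  pp <- preprocess_subject(s$trace, s$beh$trials, cfg)
  ok <- pp$trials$included & is.finite(pp$trials$phasic_scalar)
  rho <- cor(pp$trials$phasic_scalar[ok], s$beh$truth$arousal[ok],
             method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("early-window scalars are unbiased between go and no-go trials", {
  # motor transient rides on go trials only, but the stimulus-locked
  # window ends before the fastest admissible response
  spec <- task_spec("gonogo", trials_per_subject = 400,
                    sampling_rate_hz = 100)
  design <- make_gonogo_design(spec, seed = 5)
  coup <- arousal_coupling_spec(coupling_gamma = 0, noise_sd = 0.05,
                                blink_rate_hz = 0,
                                motor_transient_amp = 2,
                                arousal_sdlog = 0.5)
  v <- setNames(rep(0.8, 5), as.character(spec$loudness_levels))
  params <- ddm_params(v = c(v, noise = -0.8), v_bias = 0, a = 1.2,
                       t0 = 0.6)
  beh <- simulate_subject_behavior(design, params, coup, seed = 5,
                                   task = "gonogo")
  trace <- synthesize_pupil_traces(design, beh$truth, beh$trials, coup,
                                   spec, seed = 5)
  cfg <- preproc_config(species = "human", task_kind = "gonogo")
  nt <- normalize_downsample(clean_trace(trace, cfg), cfg)
  dv <- compute_derivative(nt, cfg)
  tr <- extract_phasic_scalar(dv, nt, beh$trials, cfg)
  tr$arousal <- beh$truth$arousal
  tr <- exclude_fast_trials(tr, cfg)
  ok <- tr$included
  # regress out arousal, compare residual scalar between choices
  res <- residuals(lm(phasic_scalar ~ arousal, data = tr[ok, ]))
  go <- tr$choice[ok] == 1
  # any motor leakage into the early window stays well below the
  # arousal-driven scalar spread
  expect_lt(abs(mean(res[go]) - mean(res[!go])),
            0.15 * sd(tr$phasic_scalar[ok]))
})

test_that("written datasets are byte-identical across runs with one seed", {
  spec <- task_spec("yesno", n_subjects = 2, trials_per_subject = 40,
                    sampling_rate_hz = 100)
  params <- ddm_params(v = 1, v_bias = -0.3, a = 1, t0 = 0.4)
  coup <- arousal_coupling_spec()
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  generate_dataset(spec, params, coup, out_dir = d1, seed = 9)
  generate_dataset(spec, params, coup, out_dir = d2, seed = 9)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  trials <- read.table(file.path(d1, "trials.tsv"), header = TRUE,
                       sep = "\t")
  expect_equal(nrow(trials), 80)
  expect_true(all(c("subject_id", "signal_present", "choice",
                    "rt_s") %in% names(trials)))
  unlink(c(d1, d2), recursive = TRUE)
})
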