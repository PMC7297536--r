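#' Synthesize a pupil trace for one subject's session
#'
#' Builds `trace = baseline drift + sum_t arousal_t * IRF(t - onset_t) +
#' motor transient * IRF(t - response_t) (go/yes choices only) + noise`,
#' then inserts blink gaps (missing samples, 100--400 ms, overlapping gaps
#' merged) followed by a small blink-evoked dilation so the deconvolution
#' stage has a real artifact to remove. Event annotations (trial onsets,
#' responses, blink offsets) are attached to the returned trace.
#'
#' @param design design table (defines trial count and ordering).
#' @param truth ground-truth list from [simulate_subject_behavior()]
#'   (provides per-trial `arousal`).
#' @param trials trial table with `choice` and `rt_s` (for motor events).
#' @param coupling an [arousal_coupling_spec()].
#' @param spec the [task_spec()] (timing and sampling rate).
#' @param seed integer seed.
#' @param dc mean pupil level (arbitrary units) the modulations ride on.
#' @return a [pupil_trace()].
#' @export
synthesize_pupil_traces <- function(design, truth, trials, coupling, spec,
                                    seed = 1, dc = 100) {
  stopifnot(inherits(coupling, "arousal_coupling_spec"),
            inherits(spec, "task_spec"))
  set.seed(derive_seed(seed, 21L))
  fs <- spec$sampling_rate_hz
  n_tr <- nrow(design)
  step <- spec$trial_dur_s + spec$iti_s
  pad <- 2
  onsets <- pad + (seq_len(n_tr) - 1) * step
  dur <- pad * 2 + n_tr * step
  n <- round(dur * fs)
  tt <- (seq_len(n) - 1) / fs

  # slow baseline wander: heavily smoothed white noise
  drift <- rnorm(n)
  win <- max(1L, round(10 * fs))  # ~10 s moving average
  kernel <- rep(1 / win, win)
  drift <- stats::filter(drift, kernel, sides = 2, circular = TRUE)
  drift <- as.numeric(drift)
  if (sd(drift) > 0) drift <- drift / sd(drift)
  x <- dc + coupling$baseline_drift_amp * drift

  irf_len <- round(4 * fs)
  irf <- pupil_irf((seq_len(irf_len)) / fs, coupling$irf_tmax_s,
                   coupling$irf_shape)
  add_kernel <- function(x, at_s, amp) {
    i0 <- round(at_s * fs) + 1L
    span <- i0:min(n, i0 + irf_len - 1L)
    if (length(span) < 1 || i0 > n) return(x)
    x[span] <- x[span] + amp * irf[seq_along(span)]
    x
  }
  for (i in seq_len(n_tr))
    x <- add_kernel(x, onsets[i], coupling$irf_amp * truth$arousal[i])

  resp_times <- rep(NA_real_, n_tr)
  go <- !is.na(trials$choice) & trials$choice == 1 & is.finite(trials$rt_s)
  resp_times[go] <- onsets[go] + trials$rt_s[go]
  if (coupling$motor_transient_amp != 0) {
    for (i in which(go))
      x <- add_kernel(x, resp_times[i], coupling$motor_transient_amp)
  }
  if (coupling$noise_sd > 0) x <- x + rnorm(n, sd = coupling$noise_sd)

  # blink gaps: Poisson count, merged if overlapping, never negative
  missing <- rep(FALSE, n)
  blink_off <- numeric(0)
  if (coupling$blink_rate_hz > 0) {
    nb <- rpois(1, coupling$blink_rate_hz * dur)
    if (nb > 0) {
      starts <- sort(runif(nb, 0, dur - 0.5))
      lens <- runif(nb, 0.1, 0.4)
      ends <- pmin(starts + lens, dur)
      merged <- data.frame(s = starts[1], e = ends[1])
      if (nb > 1) for (i in 2:nb) {
        if (starts[i] <= merged$e[nrow(merged)]) {
          merged$e[nrow(merged)] <- max(merged$e[nrow(merged)], ends[i])
        } else merged <- rbind(merged, data.frame(s = starts[i],
                                                  e = ends[i]))
      }
      for (i in seq_len(nrow(merged))) {
        i0 <- max(1L, round(merged$s[i] * fs))
        i1 <- min(n, round(merged$e[i] * fs))
        missing[i0:i1] <- TRUE
        x <- add_kernel(x, merged$e[i], coupling$blink_response_amp)
      }
      blink_off <- merged$e
    }
  }

  events <- rbind(
    data.frame(kind = "trial_onset", time_s = onsets),
    if (any(go)) data.frame(kind = "response",
                            time_s = resp_times[go]) else NULL,
    if (length(blink_off)) data.frame(kind = "blink",
                                      time_s = blink_off) else NULL)
  events <- events[order(events$time_s), ]
  rownames(events) <- NULL
  pupil_trace(x, fs, missing = missing, events = events)
}
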