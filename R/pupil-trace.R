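#' Uniformly sampled pupil-diameter trace
#'
#' Container for a pupil time series: samples (arbitrary units, later
#' percent signal change), a missing-sample mask, event annotations
#' (trial onsets, responses, blinks, saccades) and the sampling rate.
#'
#' @param samples numeric vector of pupil values.
#' @param rate_hz sampling rate.
#' @param missing logical mask, same length as `samples`.
#' @param events data.frame with columns `kind` (one of `trial_onset`,
#'   `response`, `blink`, `saccade`) and `time_s`.
#' @param t0 time of the first sample (seconds).
#' @return an object of class `pupil_trace` with fields `samples`,
#'   `time`, `missing`, `events`, `rate_hz`.
#' @export
pupil_trace <- function(samples, rate_hz,
                        missing = rep(FALSE, length(samples)),
                        events = data.frame(kind = character(),
                                            time_s = numeric()),
                        t0 = 0) {
  stopifnot(length(missing) == length(samples), rate_hz > 0)
  structure(list(samples = as.numeric(samples),
                 time = t0 + (seq_along(samples) - 1) / rate_hz,
                 missing = as.logical(missing),
                 events = events, rate_hz = rate_hz),
            class = "pupil_trace")
}

#' @export
print.pupil_trace <- function(x, ...) {
  cat(sprintf("pupil_trace: %d samples at %g Hz (%.1f s), %.1f%% missing, %d events\n",
              length(x$samples), x$rate_hz,
              length(x$samples) / x$rate_hz,
              100 * mean(x$missing), nrow(x$events)))
  invisible(x)
}

event_times <- function(trace, kind) {
  trace$events$time_s[trace$events$kind == kind]
}

#' Canonical pupil impulse response
#'
#' Gamma-family kernel `h(t) = (t / t_max)^w exp(-w (t / t_max - 1))`,
#' peaking at `t_max` with unit amplitude; the standard pupillometry
#' convention (defaults `t_max = 0.93` s, `w = 10.1`).
#'
#' @param t times in seconds (>= 0; negative times return 0).
#' @param tmax peak time (s).
#' @param shape dimensionless shape `w`.
#' @return kernel values.
#' @export
pupil_irf <- function(t, tmax = 0.93, shape = 10.1) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (t[pos] / tmax)^shape * exp(-shape * (t[pos] / tmax - 1))
  out
}
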