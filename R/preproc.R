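#' Preprocessing configuration
#'
#' Constants of the pupil pipeline. Defaults follow the published
#' convention: interpolation pads gaps by 150 ms on both sides; a
#' third-order zero-phase Butterworth low-pass at 6 Hz cleans the trace
#' and one at 2 Hz smooths the derivative; traces are converted to
#' percent signal change around the session mean and decimated to 50 Hz.
#' The phasic scalar is the 95th percentile of the derivative in a
#' task-dependent window: 0.23--0.50 s after trial onset for human
#' go/no-go, 0.04--0.23 s for mouse go/no-go, or the 500 ms before the
#' button press (choice-locked) for yes/no tasks; the RT exclusion cutoff
#' is the window end plus a 50 ms buffer (0.55 s human, 0.28 s mouse).
#'
#' @param species `"human"` or `"mouse"`.
#' @param task_kind `"gonogo"`, `"yesno"` or `"recognition"`.
#' @param interp_pad_s gap padding for interpolation (s).
#' @param lowpass_cut_hz trace low-pass cutoff (Hz).
#' @param deriv_lowpass_cut_hz derivative low-pass cutoff (Hz).
#' @param target_rate_hz downsampling target (Hz).
#' @param deconv_epoch_s length of the deconvolution FIR epoch (s).
#' @param scalar_window list `(reference, start_s, end_s)`; filled from
#'   species/task when `NULL`.
#' @param rt_cutoff_s fast-RT exclusion; window end + 0.05 when `NULL`.
#' @param n_bins number of equal-population arousal bins (5 for go/no-go
#'   and the 50/50 yes/no task; 3 for biased yes/no; 2 for recognition).
#' @param baseline_window_s pre-trial baseline window (s).
#' @param scalar_percentile percentile of the derivative (default 0.95).
#' @return an object of class `preproc_config`.
#' @export
preproc_config <- function(species = c("human", "mouse"),
                           task_kind = c("gonogo", "yesno", "recognition"),
                           interp_pad_s = 0.15,
                           lowpass_cut_hz = 6,
                           deriv_lowpass_cut_hz = 2,
                           target_rate_hz = 50,
                           deconv_epoch_s = 6,
                           scalar_window = NULL,
                           rt_cutoff_s = NULL,
                           n_bins = NULL,
                           baseline_window_s = 0.5,
                           scalar_percentile = 0.95) {
  species <- match.arg(species)
  task_kind <- match.arg(task_kind)
  if (is.null(scalar_window)) {
    scalar_window <- if (task_kind == "gonogo") {
      if (species == "mouse") list(reference = "stimulus",
                                   start_s = 0.04, end_s = 0.23)
      else list(reference = "stimulus", start_s = 0.23, end_s = 0.50)
    } else list(reference = "choice", start_s = -0.5, end_s = 0)
  }
  if (scalar_window$start_s >= scalar_window$end_s)
    stop("scalar window must be well-ordered")
  if (is.null(rt_cutoff_s)) {
    rt_cutoff_s <- if (task_kind == "gonogo")
      scalar_window$end_s + 0.05 else 0
  }
  if (is.null(n_bins)) {
    n_bins <- switch(task_kind, gonogo = 5L, yesno = 5L,
                     recognition = 2L)
  }
  structure(list(species = species, task_kind = task_kind,
                 interp_pad_s = interp_pad_s,
                 lowpass_cut_hz = lowpass_cut_hz,
                 deriv_lowpass_cut_hz = deriv_lowpass_cut_hz,
                 target_rate_hz = target_rate_hz,
                 deconv_epoch_s = deconv_epoch_s,
                 scalar_window = scalar_window,
                 rt_cutoff_s = rt_cutoff_s, n_bins = as.integer(n_bins),
                 baseline_window_s = baseline_window_s,
                 scalar_percentile = scalar_percentile),
            class = "preproc_config")
}

# zero-phase third-order Butterworth low-pass; cutoff must be below
# Nyquist. Odd-reflection padding at both ends suppresses the filter's
# edge transients (same convention as scipy's filtfilt).
butter_lowpass <- function(x, cutoff_hz, rate_hz) {
  if (cutoff_hz >= rate_hz / 2)
    stop("low-pass cutoff at or above Nyquist")
  bf <- signal::butter(3, cutoff_hz / (rate_hz / 2), type = "low")
  n <- length(x)
  m <- mean(x)
  xc <- x - m
  pad <- min(n - 1, max(100, round(10 * rate_hz / cutoff_hz)))
  front <- 2 * xc[1] - xc[(pad + 1):2]
  back <- 2 * xc[n] - xc[(n - 1):(n - pad)]
  y <- as.numeric(signal::filtfilt(bf, c(front, xc, back)))
  y[(pad + 1):(pad + n)] + m
}

#' Interpolate missing samples and low-pass filter a trace
#'
#' Step (i)+(ii) of the pipeline: each missing-data gap, extended by
#' `interp_pad_s` on both sides, is replaced by linear interpolation
#' between the nearest valid anchors; gaps touching a trace edge are held
#' at the nearest valid value. The result is low-pass filtered with a
#' zero-phase third-order Butterworth at `lowpass_cut_hz`. Idempotent: a
#' second application changes nothing (no gaps remain). Sessions with
#' more than 40% missing samples are flagged with a warning.
#'
#' @param trace a [pupil_trace()].
#' @param config a [preproc_config()].
#' @return a cleaned [pupil_trace()] (mask all `FALSE`).
#' @export
clean_trace <- function(trace, config = preproc_config()) {
  stopifnot(inherits(trace, "pupil_trace"))
  x <- trace$samples
  n <- length(x)
  bad <- trace$missing | !is.finite(x)
  if (all(bad)) stop("trace is fully missing")
  if (mean(bad) > 0.4)
    warning("more than 40% of samples missing in this session")
  if (any(bad)) {
    pad <- round(config$interp_pad_s * trace$rate_hz)
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      s <- max(1L, starts[i] - pad)
      e <- min(n, ends[i] + pad)
      bad[s:e] <- TRUE
    }
    good <- which(!bad)
    xi <- approx(x = good, y = x[good], xout = seq_len(n),
                 rule = 2)$y
    x <- xi
  }
  y <- butter_lowpass(x, config$lowpass_cut_hz, trace$rate_hz)
  out <- trace
  out$samples <- y
  out$missing <- rep(FALSE, n)
  out
}

#' Remove blink- and saccade-evoked pupil responses by deconvolution
#'
#' Step (iii), used for human-style traces: finite-impulse-response
#' estimates of the blink- and saccade-evoked responses are obtained by
#' least squares on a lagged event design matrix spanning
#' `deconv_epoch_s` (event anchor = blink/saccade offset), and the fitted
#' event-locked contributions are subtracted from the trace. With no
#' events the trace is returned unchanged; with fewer events than needed
#' for identifiability removal is skipped with a warning.
#'
#' @param trace a cleaned [pupil_trace()].
#' @param config a [preproc_config()].
#' @param kinds event kinds to model (default blink and saccade).
#' @param min_events minimum events per kind for removal.
#' @return the trace with event-locked responses removed; the estimated
#'   kernels are attached as attribute `"fir"`.
#' @export
deconvolve_artifacts <- function(trace, config = preproc_config(),
                                 kinds = c("blink", "saccade"),
                                 min_events = 2) {
  stopifnot(inherits(trace, "pupil_trace"))
  n <- length(trace$samples)
  L <- round(config$deconv_epoch_s * trace$rate_hz)
  use <- kinds[vapply(kinds, function(k)
    length(event_times(trace, k)) >= min_events, TRUE)]
  dropped <- setdiff(kinds[vapply(kinds, function(k)
    length(event_times(trace, k)) > 0, TRUE)], use)
  if (length(dropped))
    warning("too few events for identifiable deconvolution of: ",
            paste(dropped, collapse = ", "), "; skipped")
  if (!length(use)) return(trace)

  ij <- list()
  for (ki in seq_along(use)) {
    ev <- event_times(trace, use[ki])
    idx0 <- round((ev - trace$time[1]) * trace$rate_hz) + 1L
    for (i0 in idx0) {
      rows <- i0:min(n, i0 + L - 1L)
      rows <- rows[rows >= 1]
      ij[[length(ij) + 1]] <- cbind(rows,
                                    (ki - 1L) * L + seq_along(rows))
    }
  }
  ij <- do.call(rbind, ij)
  # event FIR columns plus an intercept so the baseline level does not
  # leak into the kernels
  nc <- length(use) * L
  X <- Matrix::sparseMatrix(i = c(ij[, 1], seq_len(n)),
                            j = c(ij[, 2], rep(nc + 1L, n)),
                            x = 1, dims = c(n, nc + 1L))
  y <- trace$samples
  XtX <- Matrix::crossprod(X)
  Xty <- Matrix::crossprod(X, y)
  beta <- as.numeric(Matrix::solve(XtX + Matrix::Diagonal(ncol(X), 1e-8),
                                   Xty))
  beta_ev <- beta
  beta_ev[nc + 1L] <- 0  # subtract event-locked contributions only
  fitted <- as.numeric(X %*% beta_ev)
  out <- trace
  out$samples <- trace$samples - fitted
  fir <- lapply(seq_along(use),
                function(ki) beta[(ki - 1L) * L + seq_len(L)])
  names(fir) <- use
  attr(out, "fir") <- fir
  out
}

#' Convert to percent signal change and downsample
#'
#' Steps (iv)+(v): samples become `100 (x - mean) / mean` around the
#' session mean, then the trace is decimated to `target_rate_hz` with an
#' anti-aliasing low-pass (zero-phase Butterworth at 80% of the new
#' Nyquist). The source rate must be an integer multiple of the target.
#'
#' @param trace a cleaned [pupil_trace()].
#' @param config a [preproc_config()].
#' @return the normalized, downsampled [pupil_trace()] (units: % signal
#'   change).
#' @export
normalize_downsample <- function(trace, config = preproc_config()) {
  stopifnot(inherits(trace, "pupil_trace"))
  m <- mean(trace$samples)
  if (!is.finite(m) || m <= 0)
    stop("session mean must be positive for percent-signal-change units")
  x <- 100 * (trace$samples - m) / m
  fs <- trace$rate_hz
  target <- config$target_rate_hz
  if (fs < target) stop("trace rate below target rate")
  fac <- fs / target
  if (abs(fac - round(fac)) > 1e-9)
    stop("source rate must be an integer multiple of the target rate")
  fac <- round(fac)
  if (fac > 1) {
    x <- butter_lowpass(x, 0.8 * (target / 2), fs)
    x <- x[seq(1, length(x), by = fac)]
  }
  pupil_trace(x, target, events = trace$events, t0 = trace$time[1])
}

#' First time derivative of the pupil trace
#'
#' Adjacent-sample difference scaled to per-second units (%/s), then
#' zero-phase third-order Butterworth low-pass at
#' `deriv_lowpass_cut_hz`. The first sample repeats the first difference
#' so the output length matches the input.
#'
#' @param trace a normalized [pupil_trace()].
#' @param config a [preproc_config()].
#' @return a [pupil_trace()] of the derivative (units %/s).
#' @export
compute_derivative <- function(trace, config = preproc_config()) {
  stopifnot(inherits(trace, "pupil_trace"))
  x <- trace$samples
  if (length(x) < 24) stop("trace shorter than the filter pad")
  d <- diff(x) * trace$rate_hz
  d <- c(d[1], d)
  d <- butter_lowpass(d, config$deriv_lowpass_cut_hz, trace$rate_hz)
  out <- trace
  out$samples <- d
  out
}
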