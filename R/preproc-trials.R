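#' Per-trial phasic-arousal scalar and baseline
#'
#' The phasic scalar is the 95th percentile of the pupil derivative in the
#' configured window (stimulus-locked after trial onset for go/no-go,
#' choice-locked before the button press for yes/no); the baseline is the
#' mean of the normalized (non-derivative) trace in the
#' `baseline_window_s` before trial onset. Trials whose window holds
#' fewer than two samples (or, for choice-locking, that have no response)
#' are flagged excluded.
#'
#' @param deriv_trace derivative [pupil_trace()] from
#'   [compute_derivative()].
#' @param norm_trace normalized [pupil_trace()] from
#'   [normalize_downsample()] (baseline source).
#' @param trials trial table; onsets are taken from the trace's
#'   `trial_onset` events (in trial order) and response times from
#'   `onset + rt_s`.
#' @param config a [preproc_config()].
#' @return `trials` with added `phasic_scalar`, `baseline_pupil`,
#'   `included` columns.
#' @export
extract_phasic_scalar <- function(deriv_trace, norm_trace, trials,
                                  config = preproc_config()) {
  stopifnot(inherits(deriv_trace, "pupil_trace"),
            inherits(norm_trace, "pupil_trace"))
  onsets <- event_times(deriv_trace, "trial_onset")
  if (length(onsets) != nrow(trials))
    stop("number of trial_onset events does not match trial table")
  w <- config$scalar_window
  fs <- deriv_trace$rate_hz
  t0 <- deriv_trace$time[1]
  nd <- length(deriv_trace$samples)
  scalar <- baseline <- rep(NA_real_, nrow(trials))
  included <- rep(TRUE, nrow(trials))
  for (i in seq_len(nrow(trials))) {
    anchor <- if (w$reference == "stimulus") onsets[i]
      else if (is.finite(trials$rt_s[i])) onsets[i] + trials$rt_s[i]
      else NA_real_
    if (is.na(anchor)) { included[i] <- FALSE; next }
    # samples whose timestamps fall inside [start, end]
    i0 <- as.integer(ceiling((anchor + w$start_s - t0) * fs - 1e-6)) + 1L
    i1 <- as.integer(floor((anchor + w$end_s - t0) * fs + 1e-6)) + 1L
    if (i0 < 1 || i1 > nd || i1 - i0 < 1) { included[i] <- FALSE; next }
    scalar[i] <- quantile(deriv_trace$samples[i0:i1],
                          config$scalar_percentile, type = 7,
                          names = FALSE)
    b0 <- floor((onsets[i] - config$baseline_window_s - t0) *
                  norm_trace$rate_hz) + 1L
    b1 <- floor((onsets[i] - t0) * norm_trace$rate_hz) + 1L
    if (b0 >= 1 && b1 <= length(norm_trace$samples) && b1 > b0)
      baseline[i] <- mean(norm_trace$samples[b0:b1])
  }
  trials$phasic_scalar <- scalar
  trials$baseline_pupil <- baseline
  trials$included <- included
  trials
}

#' Exclude fast-RT and cue trials
#'
#' Go/yes choices faster than `rt_cutoff_s` are removed (the scalar
#' window end plus a 50 ms buffer by default: 280 ms for mice, 550 ms for
#' humans); no-go trials (absent RT) are always retained; the first trial
#' of each mini-block (cue trial) is removed.
#'
#' @param trials trial table with `choice`, `rt_s` and optionally
#'   `is_cue_trial`.
#' @param config a [preproc_config()].
#' @return the filtered trial table.
#' @export
exclude_fast_trials <- function(trials, config = preproc_config()) {
  fast <- !is.na(trials$choice) & trials$choice == 1 &
    is.finite(trials$rt_s) & trials$rt_s < config$rt_cutoff_s
  keep <- !fast
  if ("is_cue_trial" %in% names(trials))
    keep <- keep & !(trials$is_cue_trial %in% 1L)
  trials[keep, , drop = FALSE]
}

#' Assign equal-population arousal bins
#'
#' Included trials are ranked by `phasic_scalar` within each stratum
#' (e.g. loudness level; the whole set when unstratified) and split into
#' `n_bins` bins whose populations differ by at most one; ties keep their
#' original order (stable ranking). Bin 0 is lowest arousal.
#'
#' @param trials trial table with `phasic_scalar` (and `included` if
#'   present).
#' @param config a [preproc_config()].
#' @param stratify_by optional column name (e.g. `"loudness_db"`).
#' @return `trials` with an integer `pupil_bin` column in
#'   `[0, n_bins)` (`NA` for excluded trials).
#' @export
assign_pupil_bins <- function(trials, config = preproc_config(),
                              stratify_by = NULL) {
  if (!"phasic_scalar" %in% names(trials))
    stop("`phasic_scalar` missing; run extract_phasic_scalar() first")
  inc <- if ("included" %in% names(trials)) trials$included &
    is.finite(trials$phasic_scalar) else is.finite(trials$phasic_scalar)
  nb <- config$n_bins
  bin <- rep(NA_integer_, nrow(trials))
  strata <- if (is.null(stratify_by)) factor(rep(1, nrow(trials)))
    else {
      s <- as.character(trials[[stratify_by]])
      factor(ifelse(is.na(s), "(none)", s))  # noise trials: own stratum
    }
  for (s in levels(strata)) {
    idx <- which(inc & strata == s)
    m <- length(idx)
    if (!m) next
    if (m < nb)
      warning("stratum with fewer trials than bins; bins of size >= 1 where possible")
    ord <- idx[order(trials$phasic_scalar[idx])] # stable: ties keep order
    bin[ord] <- as.integer(ceiling(seq_len(m) * min(nb, m) / m) - 1L)
  }
  trials$pupil_bin <- bin
  trials
}

#' Run the full preprocessing chain on one subject
#'
#' clean -> (deconvolve) -> normalize/downsample -> derivative -> scalar
#' extraction -> exclusions -> binning. Deconvolution is applied for
#' human-style traces and skipped for mouse traces.
#'
#' @param trace raw [pupil_trace()].
#' @param trials this subject's trial table.
#' @param config a [preproc_config()].
#' @param stratify_by passed to [assign_pupil_bins()].
#' @return list with the augmented `trials`, the normalized `trace` and
#'   the `deriv` trace.
#' @export
preprocess_subject <- function(trace, trials, config = preproc_config(),
                               stratify_by = NULL) {
  tr <- clean_trace(trace, config)
  if (config$species == "human")
    tr <- suppressWarnings(deconvolve_artifacts(tr, config))
  nt <- normalize_downsample(tr, config)
  dv <- compute_derivative(nt, config)
  trials <- extract_phasic_scalar(dv, nt, trials, config)
  trials <- exclude_fast_trials(trials, config)
  trials <- assign_pupil_bins(trials, config, stratify_by = stratify_by)
  list(trials = trials, trace = nt, deriv = dv)
}
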