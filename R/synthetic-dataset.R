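#' Generate a complete synthetic dataset on disk
#'
#' Runs design generation, behavioral simulation and pupil-trace
#' synthesis for every subject and writes: a tab-delimited trial table
#' (`trials.tsv`), one trace file per subject (`trace_s<k>.tsv`: time_s,
#' pupil_au, missing) and a JSON ground-truth sidecar (`truth.json`,
#' generative parameters and per-trial latent arousal). Byte-identical
#' across runs for a fixed seed and config.
#'
#' @param spec a [task_spec()].
#' @param params generative [ddm_params()] (subject baselines may be
#'   overridden per subject via `bias_base`).
#' @param coupling an [arousal_coupling_spec()].
#' @param bias_base optional vector (length `n_subjects`) of per-subject
#'   baseline drift biases; defaults to `params$v_bias` for all.
#' @param out_dir output directory (created if needed); `NULL` returns
#'   the in-memory dataset without writing.
#' @param seed integer master seed (fanned out to per-subject substreams).
#' @return (invisibly when writing) list with `trials` (all subjects),
#'   `traces` (list of [pupil_trace()]), `truth` (per-subject list),
#'   `spec`, `params`, `coupling`.
#' @export
generate_dataset <- function(spec, params, coupling, bias_base = NULL,
                             out_dir = NULL, seed = 1) {
  stopifnot(inherits(spec, "task_spec"))
  if (is.null(bias_base)) bias_base <- rep(params$v_bias, spec$n_subjects)
  stopifnot(length(bias_base) == spec$n_subjects)
  task <- if (spec$task_kind == "gonogo") "gonogo" else "yesno"
  all_trials <- list()
  traces <- list()
  truths <- list()
  for (s in seq_len(spec$n_subjects)) {
    sseed <- derive_seed(seed, 1000L + s)
    design <- if (spec$task_kind == "gonogo")
      make_gonogo_design(spec, seed = sseed)
    else make_yesno_design(spec, seed = sseed)
    p_s <- params
    p_s$v_bias <- bias_base[s]
    beh <- simulate_subject_behavior(design, p_s, coupling, seed = sseed,
                                     task = task)
    tr <- beh$trials
    tr <- cbind(data.frame(subject_id = s, session = 1L,
                           task = spec$task_kind), tr)
    if (!"miniblock" %in% names(tr)) tr$miniblock <- NA_integer_
    if (!"block" %in% names(tr)) tr$block <- NA_integer_
    if (!"is_cue_trial" %in% names(tr)) tr$is_cue_trial <- 0L
    all_trials[[s]] <- tr[, c("subject_id", "session", "task", "block",
                              "miniblock", "trial_idx", "is_cue_trial",
                              "signal_present", "loudness_db", "choice",
                              "rt_s", "correct")]
    traces[[s]] <- synthesize_pupil_traces(design, beh$truth, beh$trials,
                                           coupling, spec, seed = sseed)
    truths[[s]] <- list(subject_id = s, bias_base = bias_base[s],
                        arousal = beh$truth$arousal,
                        effective_bias = beh$truth$effective_bias)
  }
  trials <- do.call(rbind, all_trials)
  ds <- list(trials = trials, traces = traces, truth = truths,
             spec = spec, params = params, coupling = coupling)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir))
      dir.create(out_dir, recursive = TRUE)
    write.table(trials, file.path(out_dir, "trials.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (s in seq_len(spec$n_subjects)) {
      tr <- traces[[s]]
      write.table(data.frame(time_s = round(tr$time, 6),
                             pupil_au = round(tr$samples, 6),
                             missing = as.integer(tr$missing)),
                  file.path(out_dir, sprintf("trace_s%02d.tsv", s)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(tr$events,
                  file.path(out_dir, sprintf("events_s%02d.tsv", s)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    gt <- list(params = params[c("v", "v_bias", "z_rel", "a", "t0",
                                 "sv", "s", "tau_urgency")],
               coupling = unclass(coupling),
               subjects = truths)
    jsonlite::write_json(gt, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(ds))
  }
  ds
}
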