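#' Task specification for the synthetic-data generator
#'
#' Defaults encode the study designs the generator emulates: go/no-go
#' mini-blocks of 2--7 one-second trials whose unique signal falls on the
#' final trial (so the marginal probability of the signal declines with
#' within-block position), and yes/no (or old/new recognition) sessions
#' with stratified signal probability 0.5, 0.3 or 0.7.
#'
#' @param task_kind `"gonogo"`, `"yesno"`, or `"recognition"`.
#' @param n_subjects number of subjects.
#' @param trials_per_subject target trials per subject. Default 660 for the
#'   human go/no-go configuration; use `species = "mouse"` for the
#'   2469--3479 range.
#' @param signal_prob signal probability (yes/no only; 0.5, 0.3 or 0.7).
#' @param loudness_levels dB offsets of the signal levels (go/no-go).
#' @param miniblock_range integer pair, allowed mini-block lengths
#'   (default `c(2, 7)`).
#' @param trial_dur_s,iti_s trial duration and inter-trial interval
#'   (seconds).
#' @param sampling_rate_hz pupil sampling rate of generated traces.
#' @param species `"human"` or `"mouse"`; sets loudness levels, trial
#'   counts and downstream extraction windows.
#' @param block_geom_p truncated-geometric parameter of the block-length
#'   distribution.
#' @return an object of class `task_spec`.
#' @export
task_spec <- function(task_kind = c("gonogo", "yesno", "recognition"),
                      n_subjects = 10,
                      trials_per_subject = NULL,
                      signal_prob = 0.5,
                      loudness_levels = NULL,
                      miniblock_range = c(2L, 7L),
                      trial_dur_s = 1.0, iti_s = NULL,
                      sampling_rate_hz = 100,
                      species = c("human", "mouse"),
                      block_geom_p = 0.25) {
  task_kind <- match.arg(task_kind)
  species <- match.arg(species)
  if (miniblock_range[1] < 2 || miniblock_range[2] > 7 ||
      miniblock_range[1] > miniblock_range[2])
    stop("`miniblock_range` must satisfy 2 <= low <= high <= 7")
  if (task_kind == "yesno" && (signal_prob <= 0 || signal_prob >= 1))
    stop("`signal_prob` must lie in (0, 1)")
  if (is.null(loudness_levels)) {
    loudness_levels <- if (task_kind != "gonogo") 0
      else if (species == "human") c(-40, -30, -20, -10, -5)
      else c(-30, -24, -18, -12, -6, 0)
  }
  if (!length(loudness_levels)) stop("`loudness_levels` must be nonempty")
  if (is.null(trials_per_subject)) {
    trials_per_subject <- switch(task_kind,
      gonogo = if (species == "human") 660L else NA_integer_,
      yesno = 1320L, recognition = 300L)
  }
  # go/no-go trials follow each other every 1.5 s; yes/no trials are
  # separated by a 3-4 s baseline interval
  if (is.null(iti_s)) iti_s <- if (task_kind == "gonogo") 0.5 else 3.5
  structure(list(task_kind = task_kind, n_subjects = n_subjects,
                 trials_per_subject = trials_per_subject,
                 signal_prob = signal_prob,
                 loudness_levels = loudness_levels,
                 miniblock_range = as.integer(miniblock_range),
                 trial_dur_s = trial_dur_s, iti_s = iti_s,
                 sampling_rate_hz = sampling_rate_hz,
                 species = species, block_geom_p = block_geom_p),
            class = "task_spec")
}

# block lengths: truncated geometric on {lo..hi}; pmf decreasing, so the
# marginal probability that the signal falls at position k declines with k
draw_block_lengths <- function(n, lo, hi, p) {
  if (lo == hi) return(rep(lo, n))
  k <- lo:hi
  pmf <- p * (1 - p)^(k - lo)
  pmf <- pmf / sum(pmf)
  k[sample.int(length(k), n, replace = TRUE, prob = pmf)]
}

#' Generate a go/no-go mini-block design
#'
#' Mini-blocks of consecutive one-second trials; every block carries its
#' unique signal on the final trial, so longer blocks imply a signal that
#' arrives later and the marginal signal probability declines with
#' within-block trial index. The first trial of every block is a cue
#' trial (never a signal; excluded from analysis downstream). Signal
#' loudness is balanced across blocks in chunks of 60 mini-blocks.
#'
#' @param spec a [task_spec()] with `task_kind = "gonogo"`.
#' @param seed integer seed.
#' @return design data.frame with columns `miniblock`, `trial_idx`
#'   (within block), `is_cue_trial`, `signal_present`, `loudness_db`.
#' @export
make_gonogo_design <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "task_spec"))
  if (spec$task_kind != "gonogo") stop("spec must have task_kind 'gonogo'")
  set.seed(seed)
  target <- spec$trials_per_subject
  if (is.na(target)) # mouse default: session-count variability
    target <- sample(2469:3479, 1)
  lo <- spec$miniblock_range[1]; hi <- spec$miniblock_range[2]
  lens <- integer(0)
  while (sum(lens) < target) {
    lens <- c(lens, draw_block_lengths(
      max(16, ceiling((target - sum(lens)) / lo)), lo, hi,
      spec$block_geom_p))
    if (sum(lens) >= target) {
      cum <- cumsum(lens)
      nb <- which(cum >= target)[1]
      lens <- lens[seq_len(nb)]
      # walk back from the final block, trimming each to a legal length,
      # until the session size is exact
      excess <- sum(lens) - target
      i <- length(lens)
      while (excess > 0 && i >= 1) {
        red <- min(excess, lens[i] - lo)
        lens[i] <- lens[i] - red
        excess <- excess - red
        i <- i - 1
      }
      if (excess > 0) lens <- lens[seq_len(length(lens) - 1)]
    }
  }
  nb <- length(lens)
  # balanced loudness per chunk of 60 mini-blocks
  nl <- length(spec$loudness_levels)
  loud_of_block <- unlist(lapply(split(seq_len(nb),
                                       (seq_len(nb) - 1) %/% 60),
    function(ix) sample(rep(spec$loudness_levels,
                            length.out = length(ix)))))
  out <- do.call(rbind, lapply(seq_len(nb), function(b) {
    L <- lens[b]
    data.frame(miniblock = b, trial_idx = seq_len(L),
               is_cue_trial = c(1L, rep(0L, L - 1L)),
               signal_present = c(rep(0L, L - 1L), 1L),
               loudness_db = c(rep(NA_real_, L - 1L), loud_of_block[b]))
  }))
  rownames(out) <- NULL
  out
}

#' Generate a yes/no or recognition design
#'
#' Signal flags are stratified so that the session-level signal count is
#' exact (`round(signal_prob * n)`), matching per block of 120 trials.
#' Recognition designs use a 50/50 old/new split regardless of
#' `signal_prob`.
#'
#' @param spec a [task_spec()] with `task_kind` `"yesno"` or
#'   `"recognition"`.
#' @param seed integer seed.
#' @return design data.frame with columns `block`, `trial_idx`,
#'   `signal_present`, `loudness_db` (fixed per subject for yes/no).
#' @export
make_yesno_design <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "task_spec"))
  if (!spec$task_kind %in% c("yesno", "recognition"))
    stop("spec must have task_kind 'yesno' or 'recognition'")
  set.seed(seed)
  n <- spec$trials_per_subject
  p <- if (spec$task_kind == "recognition") 0.5 else spec$signal_prob
  block_size <- min(120L, n)
  starts <- seq(1L, n, by = block_size)
  sig <- unlist(lapply(starts, function(s) {
    m <- min(block_size, n - s + 1L)
    k <- round(p * m)
    sample(c(rep(1L, k), rep(0L, m - k)))
  }))
  data.frame(block = rep(seq_along(starts),
                         times = diff(c(starts, n + 1L))),
             trial_idx = seq_len(n),
             signal_present = sig,
             loudness_db = ifelse(sig == 1, spec$loudness_levels[1],
                                  NA_real_))
}
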