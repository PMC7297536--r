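#' Simulate choices and response times from the drift diffusion model
#'
#' Euler--Maruyama integration of the diffusion between two (optionally
#' collapsing) bounds, with a Brownian-bridge correction for within-step
#' bound crossings so that first-passage statistics are accurate already at
#' the default step size. The per-trial mean drift is
#' `v[level] * sign + v_bias` (see below); across-trial drift variability
#' `sv` perturbs each trial's drift by a normal deviate.
#'
#' @param params a [ddm_params()] object.
#' @param n_trials number of trials; ignored when `signal` is given.
#' @param signal optional 0/1 vector of signal presence. With a single
#'   unnamed drift rate, signal trials drift at `+v`, noise trials at `-v`.
#'   With a named drift map, `loudness` selects the entry per trial and
#'   noise trials use the `"noise"` entry.
#' @param loudness optional per-trial stimulus-level labels indexing
#'   `params$v`.
#' @param seed integer seed for the simulator's own RNG.
#' @param dt integration step in seconds (default 0.001, must be <= 0.002).
#' @param t_max censoring horizon for constant bounds (seconds).
#' @param bridge logical; apply the within-step crossing correction
#'   (default `TRUE`).
#' @return data.frame with columns `choice` (1 = upper/yes, 0 = lower/no,
#'   `NA` = censored), `rt` (seconds, includes `t0`; `NA` when censored)
#'   and `censored`.
#' @export
simulate_ddm <- function(params, n_trials = NULL, signal = NULL,
                         loudness = NULL, seed = 1, dt = 0.001,
                         t_max = 20, bridge = TRUE) {
  stopifnot(inherits(params, "ddm_params"))
  if (dt > 0.002) stop("`dt` must be <= 0.002 s")
  if (is.null(signal)) {
    if (is.null(n_trials)) stop("give `n_trials` or `signal`")
    signal <- rep(1L, n_trials)
  }
  n <- length(signal)
  mu <- ddm_trial_drift(params$v, signal, loudness) + params$v_bias
  sim <- cpp_simulate_ddm(mu, params$sv, params$a, params$z_rel, params$t0,
                          params$tau_urgency, params$s, dt, t_max,
                          as.integer(seed), bridge)
  data.frame(choice = sim$choice, rt = sim$rt, censored = sim$censored)
}

# resolve per-trial stimulus drift (before bias) from a drift map
ddm_trial_drift <- function(v, signal, loudness = NULL) {
  if (length(v) == 1 && is.null(names(v))) {
    return(ifelse(signal == 1, v, -v))
  }
  if (is.null(names(v))) stop("multi-level drift map `v` must be named")
  mu <- numeric(length(signal))
  noise_v <- if ("noise" %in% names(v)) v[["noise"]] else -v[[1]]
  mu[signal == 0] <- noise_v
  if (any(signal == 1)) {
    if (is.null(loudness)) {
      if (!"signal" %in% names(v))
        stop("need `loudness` labels (or a \"signal\" entry) for signal trials")
      mu[signal == 1] <- v[["signal"]]
    } else {
      lab <- as.character(loudness[signal == 1])
      if (!all(lab %in% names(v)))
        stop("drift map does not cover all loudness levels")
      mu[signal == 1] <- v[lab]
    }
  }
  unname(mu)
}

#' Response-time quantile edges
#'
#' Quantile edges used to bin RT distributions for G-square fitting. The
#' default probabilities 0.1, 0.3, 0.5, 0.7, 0.9 split the distribution
#' into six bins of nominal mass 0.1, 0.2, 0.2, 0.2, 0.2, 0.1.
#'
#' @param rts numeric vector of RTs.
#' @param probs quantile probabilities.
#' @return numeric vector of quantile edges. If fewer RTs than quantiles
#'   are available the probabilities collapse to the median (with a
#'   warning); degenerate (all-equal) inputs yield equal edges.
#' @export
rt_quantiles <- function(rts, probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  rts <- rts[is.finite(rts)]
  if (length(rts) < length(probs)) {
    warning("fewer RTs than quantiles; collapsing to the median")
    probs <- 0.5
  }
  unname(quantile(rts, probs = probs, type = 7))
}

#' G-square goodness-of-fit statistic
#'
#' `G^2 = 2 * sum O_i log(O_i / (N p_i))` over bins, with `0 log 0 = 0` and
#' expected proportions floored at 1e-10.
#'
#' @param observed non-negative observed counts.
#' @param expected_p expected proportions (summing to 1 per condition).
#' @return the G-square statistic.
#' @export
gsquare_statistic <- function(observed, expected_p) {
  stopifnot(length(observed) == length(expected_p))
  cpp_gsq(as.numeric(observed), as.numeric(expected_p))
}

#' Conditional response function
#'
#' Fraction of yes (upper-bound) choices within RT quintile bins of the
#' pooled RT distribution. The shape separates starting-point from
#' drift-bias effects: a starting-point shift loads on the fastest bin,
#' a drift-bias shift moves all bins.
#'
#' @param choices 0/1 vector of choices.
#' @param rts RTs (same length).
#' @param n_bins number of quantile bins (default 5).
#' @return data.frame with columns `bin`, `rt_mean`, `frac_yes`, `n`.
#' @export
conditional_response_function <- function(choices, rts, n_bins = 5) {
  ok <- is.finite(rts) & !is.na(choices)
  choices <- choices[ok]; rts <- rts[ok]
  if (length(rts) < n_bins) stop("need at least `n_bins` trials")
  edges <- quantile(rts, probs = seq_len(n_bins - 1) / n_bins, type = 7)
  bin <- findInterval(rts, edges, left.open = TRUE) + 1L
  out <- data.frame(bin = seq_len(n_bins))
  out$rt_mean <- vapply(out$bin, function(b) mean(rts[bin == b]), 0)
  out$frac_yes <- vapply(out$bin, function(b) mean(choices[bin == b]), 0)
  out$n <- vapply(out$bin, function(b) sum(bin == b), 0L)
  out
}
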