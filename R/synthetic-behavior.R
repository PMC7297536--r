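#' Arousal-to-bias coupling specification
#'
#' The generator's latent phasic-arousal variable and its coupling to the
#' diffusion model's drift bias. Per trial, arousal is drawn from a
#' unit-median lognormal; the effective drift bias is the subject's
#' baseline bias multiplicatively suppressed toward zero,
#' `bias_t = bias_base * (1 - gamma * a_t)`, with `a_t` the arousal rank
#' normalized to \[0, 1\]. A multiplicative law is used so that biases of
#' either sign shrink toward neutral as arousal rises, which an additive
#' (liberalizing) law cannot reproduce; the law is configurable via
#' `coupling_law`.
#'
#' @param arousal_sdlog lognormal sd of the latent arousal (meanlog 0, so
#'   the median is 1).
#' @param coupling_gamma suppression gain, >= 0. At 1 the bias vanishes on
#'   the highest-arousal trial; values > 1 would flip the bias sign and
#'   are clamped (with a warning) at `-flip_cap`.
#' @param coupling_law `"multiplicative"` (default) or `"additive"`
#'   (`bias_t = bias_base - gamma * a_t * sign(bias_base)`).
#' @param flip_cap largest allowed sign-flipped fraction of the baseline
#'   bias before clamping (default 0).
#' @param irf_tmax_s,irf_shape pupil impulse-response peak time (s) and
#'   shape (dimensionless); defaults 0.93 and 10.1, the standard
#'   pupillometry convention.
#' @param irf_amp arousal-to-trace gain (trace units per unit arousal).
#' @param motor_transient_amp amplitude of the response-locked motor
#'   transient added on go/yes choices (trace units).
#' @param blink_rate_hz rate of blink gaps inserted into traces.
#' @param blink_response_amp amplitude of the blink-evoked dilation left
#'   for the deconvolution stage to remove.
#' @param baseline_drift_amp amplitude of the slow baseline wander.
#' @param noise_sd additive Gaussian noise of the trace (trace units).
#' @return an object of class `arousal_coupling_spec`.
#' @export
arousal_coupling_spec <- function(arousal_sdlog = 0.5,
                                  coupling_gamma = 1,
                                  coupling_law = c("multiplicative",
                                                   "additive"),
                                  flip_cap = 0,
                                  irf_tmax_s = 0.93, irf_shape = 10.1,
                                  irf_amp = 5,
                                  motor_transient_amp = 2,
                                  blink_rate_hz = 0.1,
                                  blink_response_amp = 1,
                                  baseline_drift_amp = 3,
                                  noise_sd = 0.5) {
  coupling_law <- match.arg(coupling_law)
  if (coupling_gamma < 0) stop("`coupling_gamma` must be >= 0")
  structure(list(arousal_sdlog = arousal_sdlog,
                 coupling_gamma = coupling_gamma,
                 coupling_law = coupling_law, flip_cap = flip_cap,
                 irf_tmax_s = irf_tmax_s, irf_shape = irf_shape,
                 irf_amp = irf_amp,
                 motor_transient_amp = motor_transient_amp,
                 blink_rate_hz = blink_rate_hz,
                 blink_response_amp = blink_response_amp,
                 baseline_drift_amp = baseline_drift_amp,
                 noise_sd = noise_sd),
            class = "arousal_coupling_spec")
}

#' Simulate one subject's choice behavior with arousal-coupled drift bias
#'
#' Draws a latent arousal value per trial, converts it to an effective
#' drift bias under the coupling law, and runs the diffusion simulator
#' with that per-trial bias. Go/no-go no-choices get `NA` RTs.
#'
#' @param design a design table from [make_gonogo_design()] or
#'   [make_yesno_design()].
#' @param params generative [ddm_params()]; `params$v_bias` is the
#'   subject's baseline bias, and `params$v` must cover the design's
#'   loudness levels (plus `"noise"`) or be a single symmetric drift.
#' @param coupling an [arousal_coupling_spec()].
#' @param seed integer seed.
#' @param task `"gonogo"` or `"yesno"`; controls RT coding of no
#'   responses.
#' @param dt simulator step (s).
#' @return list with `trials` (design plus `choice`, `rt_s`, `correct`)
#'   and `truth` (per-trial latent `arousal`, `effective_bias`, and the
#'   generative params) -- the ground-truth record for recovery tests.
#' @export
simulate_subject_behavior <- function(design, params, coupling, seed = 1,
                                      task = c("gonogo", "yesno"),
                                      dt = 0.001) {
  stopifnot(inherits(params, "ddm_params"),
            inherits(coupling, "arousal_coupling_spec"))
  task <- match.arg(task)
  n <- nrow(design)
  set.seed(derive_seed(seed, 11L))
  arousal <- rlnorm(n, meanlog = 0, sdlog = coupling$arousal_sdlog)
  a_norm <- if (n > 1) (rank(arousal, ties.method = "first") - 1) / (n - 1)
            else 0.5
  g <- coupling$coupling_gamma
  base <- params$v_bias
  eff <- if (coupling$coupling_law == "multiplicative") {
    fac <- 1 - g * a_norm
    if (any(fac < -coupling$flip_cap)) {
      warning("coupling flips bias sign beyond `flip_cap`; clamping")
      fac <- pmax(fac, -coupling$flip_cap)
    }
    base * fac
  } else {
    out <- base - sign(base) * g * a_norm * abs(base)
    out
  }
  mu <- ddm_trial_drift(params$v, design$signal_present,
                        design$loudness_db) + eff
  sim <- cpp_simulate_ddm(mu, params$sv, params$a, params$z_rel,
                          params$t0, params$tau_urgency, params$s, dt,
                          20, derive_seed(seed, 12L), TRUE)
  choice <- sim$choice
  rt <- sim$rt
  if (task == "gonogo") rt[choice == 0] <- NA_real_
  trials <- design
  trials$choice <- choice
  trials$rt_s <- rt
  trials$correct <- as.integer(choice == design$signal_present)
  list(trials = trials,
       truth = list(arousal = arousal, arousal_norm = a_norm,
                    effective_bias = eff, params = params,
                    coupling = coupling))
}
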