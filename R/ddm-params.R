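#' Diffusion-model parameter set
#'
#' Bundles the generative (or fitted) parameters of the drift diffusion
#' model: per-condition drift rates, an evidence-independent drift bias,
#' relative starting point, boundary separation, non-decision time,
#' across-trial drift variability, within-trial noise, and an optional
#' urgency time constant under which the bounds collapse hyperbolically
#' (see [bound_trajectory()]).
#'
#' @param v named numeric vector of drift rates (evidence units/s), one per
#'   stimulus level. For a symmetric yes/no setting a single unnamed value
#'   may be given; signal trials then drift at `+v`, noise trials at `-v`.
#'   A named entry `"noise"` gives the (typically negative) drift used on
#'   zero-signal trials of a go/no-go task.
#' @param v_bias drift bias, a signed constant added to the drift of every
#'   trial (positive favours yes/go).
#' @param z_rel starting point as a fraction of boundary separation, in
#'   (0, 1); 0.5 is unbiased.
#' @param a boundary separation (> 0).
#' @param t0 non-decision time in seconds (>= 0).
#' @param sv across-trial standard deviation of the drift (>= 0).
#' @param s within-trial noise standard deviation; the scaling convention,
#'   default 1.
#' @param tau_urgency urgency time constant in seconds; `Inf` (default)
#'   means constant bounds.
#' @return an object of class `ddm_params`.
#' @export
ddm_params <- function(v = 1, v_bias = 0, z_rel = 0.5, a = 1, t0 = 0.3,
                       sv = 0, s = 1, tau_urgency = Inf) {
  stopifnot(is.numeric(v), length(v) >= 1)
  if (a <= 0) stop("boundary separation `a` must be > 0")
  if (z_rel <= 0 || z_rel >= 1) stop("`z_rel` must lie in (0, 1)")
  if (t0 < 0) stop("`t0` must be >= 0")
  if (sv < 0) stop("`sv` must be >= 0")
  if (s <= 0) stop("`s` must be > 0")
  if (!is.infinite(tau_urgency) && tau_urgency <= 0)
    stop("`tau_urgency` must be > 0 when finite")
  structure(list(v = v, v_bias = v_bias, z_rel = z_rel, a = a, t0 = t0,
                 sv = sv, s = s, tau_urgency = tau_urgency),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Drift diffusion parameters\n")
  cat("  v        :", paste(signif(x$v, 4), collapse = ", "), "\n")
  cat("  v_bias   :", signif(x$v_bias, 4), "\n")
  cat("  z_rel    :", signif(x$z_rel, 4), "\n")
  cat("  a        :", signif(x$a, 4), "\n")
  cat("  t0       :", signif(x$t0, 4), "s\n")
  cat("  sv       :", signif(x$sv, 4), "\n")
  cat("  s        :", signif(x$s, 4), "\n")
  cat("  urgency  :",
      if (is.infinite(x$tau_urgency)) "none (constant bounds)"
      else paste0("tau = ", signif(x$tau_urgency, 4), " s"), "\n")
  invisible(x)
}

#' Time-varying decision bounds
#'
#' Evaluates the hyperbolically collapsing bound trajectories
#' `a_up(t) = clamp(a - a t/(t + tau), a/2, a)` and
#' `a_down(t) = clamp(a t/(t + tau), 0, a/2)`. The bounds start at `(a, 0)`
#' and meet at `a/2` exactly at `t = tau`, after which every undecided
#' accumulator is forced to terminate. With `tau = Inf` the bounds are
#' constant at `(a, 0)`.
#'
#' @param a boundary separation.
#' @param tau urgency time constant in seconds, or `Inf` for constant
#'   bounds.
#' @param t vector of times (seconds, >= 0).
#' @return a data.frame with columns `t`, `a_up`, `a_down`.
#' @export
bound_trajectory <- function(a, tau, t) {
  if (any(t < 0)) stop("`t` must be >= 0")
  if (is.infinite(tau)) {
    return(data.frame(t = t, a_up = rep(a, length(t)),
                      a_down = rep(0, length(t))))
  }
  up <- pmin(pmax(a - a * t / (t + tau), a / 2), a)
  dn <- pmin(pmax(a * t / (t + tau), 0), a / 2)
  data.frame(t = t, a_up = up, a_down = dn)
}
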