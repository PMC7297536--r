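#' Signal-detection sensitivity and criterion
#'
#' d' is the difference between the z-transformed hit and false-alarm
#' rates; the criterion c is minus their average. Rates are corrected by
#' the log-linear rule (0.5 added to every cell) before the probit
#' transform so that floor/ceiling rates stay finite.
#'
#' @param n_hit,n_miss,n_fa,n_cr trial counts of the four outcome cells.
#' @param correct apply the log-linear correction (default `TRUE`).
#' @return list with `d_prime`, `criterion`, `hit_rate`, `fa_rate`.
#' @export
sdt_d_prime_criterion <- function(n_hit, n_miss, n_fa, n_cr,
                                  correct = TRUE) {
  if (n_hit + n_miss < 1 || n_fa + n_cr < 1)
    stop("each stimulus class needs at least one trial")
  add <- if (correct) 0.5 else 0
  hr <- (n_hit + add) / (n_hit + n_miss + 2 * add)
  far <- (n_fa + add) / (n_fa + n_cr + 2 * add)
  if (hr <= 0 || hr >= 1 || far <= 0 || far >= 1)
    stop("rates must be interior; enable the correction")
  zh <- qnorm(hr); zf <- qnorm(far)
  list(d_prime = zh - zf, criterion = -(zh + zf) / 2,
       hit_rate = hr, fa_rate = far)
}

#' Composite-distribution overall choice bias
#'
#' When one decision criterion serves several signal strengths (as in a
#' go/no-go task with variable loudness), per-loudness criteria cannot be
#' compared directly. This statistic models one standard-normal noise
#' distribution and one composite signal distribution (the average of
#' unit-variance normals centered at each loudness's d'), defines the
#' zero-bias point Z as the evidence value where the two densities cross,
#' the choice point C = 0.5 d'_i + c_i (a constant across loudness levels
#' when all criteria share the same false-alarm rate), and reports
#' overall bias = C - Z. Positive values are conservative. With a single
#' loudness the statistic reduces exactly to the criterion c.
#'
#' @param metrics list of per-loudness results from
#'   [sdt_d_prime_criterion()], all computed from the same false-alarm
#'   rate.
#' @param tol tolerance for verifying that C is constant across levels.
#' @return list with `zero_bias_point`, `choice_point`, `overall_bias`,
#'   and `d_components`.
#' @export
composite_overall_bias <- function(metrics, tol = 1e-6) {
  if (inherits(metrics, "list") && !is.null(metrics$d_prime))
    metrics <- list(metrics)
  d <- vapply(metrics, `[[`, 0, "d_prime")
  cc <- vapply(metrics, `[[`, 0, "criterion")
  if (all(d <= 0)) stop("degenerate input: all d' <= 0")
  C_all <- 0.5 * d + cc
  if (diff(range(C_all)) > max(tol, 1e-9 * max(abs(C_all), 1)))
    stop("inconsistent input: C = 0.5 d' + c differs across levels; ",
         "criteria must share one false-alarm rate")
  C <- mean(C_all)
  Z <- composite_crossing(d)
  list(zero_bias_point = Z, choice_point = C, overall_bias = C - Z,
       d_components = d)
}

# root of S(x) - N(x): composite signal mixture density minus the standard
# normal density; bisection on sign-change brackets found by a scan, the
# crossing nearest mean(d)/2 wins if several exist
composite_crossing <- function(d, tol = 1e-8) {
  f <- function(x) {
    s <- vapply(x, function(xi) mean(dnorm(xi - d)), 0)
    s - dnorm(x)
  }
  lo <- min(d) / 2 - 3
  hi <- max(d) / 2 + 3
  xs <- seq(lo, hi, length.out = 2001)
  fx <- f(xs)
  sgn <- sign(fx)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  exact <- which(fx == 0)
  roots <- xs[exact]
  for (i in flips) {
    a <- xs[i]; b <- xs[i + 1]
    fa <- fx[i]
    while (b - a > tol) {
      m <- (a + b) / 2
      fm <- f(m)
      if (fm == 0) { a <- m; b <- m; break }
      if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else b <- m
    }
    roots <- c(roots, (a + b) / 2)
  }
  if (!length(roots))
    stop("no crossing of composite signal and noise densities in range")
  roots[which.min(abs(roots - mean(d) / 2))]
}

#' Pupil-linked bias-shift summaries
#'
#' Per-subject summaries of how choice bias moves across arousal bins:
#' the high-minus-low bin difference and the least-squares slope over bin
#' index, the per-bin absolute bias (suppression towards zero shows up as
#' a decline), and a sign-flipped copy of the bias values in which
#' overall-liberal subjects (overall bias < 0) are flipped so that
#' suppression has a common direction across subjects.
#'
#' @param bias_by_bin numeric vector of per-bin bias values (ordered low
#'   to high arousal) for one subject.
#' @param overall_bias the subject's overall bias (sign defines flipping).
#' @return list with `shift` (high - low), `slope`, `abs_bias`,
#'   `bias_flipped`, `flipped` (logical).
#' @export
bias_shift_metrics <- function(bias_by_bin, overall_bias) {
  if (length(bias_by_bin) < 2) stop("need at least two bins")
  nb <- length(bias_by_bin)
  flip <- overall_bias < 0
  flipped <- if (flip) -bias_by_bin else bias_by_bin
  slope <- unname(coef(stats::lm(bias_by_bin ~ seq_len(nb)))[2])
  list(shift = bias_by_bin[nb] - bias_by_bin[1],
       slope = slope,
       abs_bias = abs(bias_by_bin),
       bias_flipped = flipped,
       flipped = flip)
}
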