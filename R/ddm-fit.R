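#' Fit the drift diffusion model by RT-quantile G-square
#'
#' Per-subject quantile-based fitting. Each condition cell's RT
#' distribution is summarized by the 0.1, 0.3, 0.5, 0.7, 0.9 quantiles;
#' the resulting bin counts (both choices for a yes/no task; the yes bins
#' plus a single no-go count for a go/no-go task) enter the G-square
#' statistic, which is minimized over parameters by multi-start
#' Nelder--Mead. Expected bin probabilities come from the analytic Wiener
#' first-passage solution under constant bounds (with Gauss--Hermite
#' integration over drift variability) and from common-random-number
#' simulation when the bounds collapse (urgency models). Noise-only trials
#' form their own cell, shared across loudness conditions.
#'
#' @param trials data.frame with columns `choice` (1 = yes/go, 0 = no;
#'   for go/no-go, no-go trials have `choice = 0` and `rt = NA`), `rt`
#'   (seconds), `signal` (0/1), optionally a loudness column and a
#'   condition/bin column.
#' @param task `"yesno"` (both-choice RT quantiles) or `"gonogo"` (yes
#'   quantiles plus one no-go bin per cell).
#' @param vary_param which bias parameter varies across levels of
#'   `vary_by`: `"v_bias"`, `"z_rel"`, `"tau"`, or `"none"`.
#' @param vary_by name of the column defining the condition/bin grouping
#'   for `vary_param` (e.g. `"pupil_bin"`), or `NULL`.
#' @param drift_by optional column name (e.g. `"loudness"`); drift is then
#'   fitted per level of that column, plus a `"noise"` drift shared across
#'   levels. `NULL` fits a single symmetric drift (`+v` signal, `-v` noise).
#' @param fit_sv fit across-trial drift variability (default `TRUE`).
#' @param fit_z fit a (shared) starting point; default `FALSE` fixes
#'   `z_rel = 0.5` unless `vary_param = "z_rel"`.
#' @param fit_vbias fit a (shared) drift bias when `vary_param` is not
#'   `"v_bias"`; `FALSE` fixes it at 0 (used by the equal-complexity
#'   alternative-model comparison).
#' @param dt_sim Euler step for simulation-based expected proportions.
#' @param quantile_probs RT quantile probabilities.
#' @param n_starts number of optimizer restarts (default 5).
#' @param seed seed for restart jitter and common random numbers.
#' @param n_sim simulated trials per cell per objective evaluation for
#'   collapsing-bound cells.
#' @param s within-trial noise convention (default 1).
#' @param maxit Nelder--Mead iteration cap per start.
#' @return an object of class `ddm_fit`: list with `params` (a
#'   [ddm_params()]-like list, condition-varying entries as named vectors),
#'   `gsq`, `n_trials`, `k_params`, `bic`, `observed`, `expected`,
#'   `converged`.
#' @export
fit_ddm_quantile <- function(trials, task = c("yesno", "gonogo"),
                             vary_param = c("v_bias", "z_rel", "tau", "none"),
                             vary_by = NULL, drift_by = NULL,
                             fit_sv = TRUE, fit_z = FALSE,
                             fit_vbias = TRUE,
                             quantile_probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                             n_starts = 5, seed = 1, n_sim = 4096,
                             s = 1, dt_sim = 0.005, maxit = NULL) {
  task <- match.arg(task)
  vary_param <- match.arg(vary_param)
  stopifnot(all(c("choice", "rt", "signal") %in% names(trials)))
  if (vary_param != "none" && is.null(vary_by))
    stop("`vary_by` must name a column when `vary_param` is not \"none\"")

  # cells always split by the condition column when one is given, so that
  # constrained (shared-parameter) models are scored on the same bins as
  # their condition-varying counterparts
  groups <- if (is.null(vary_by)) factor(rep("all", nrow(trials)))
            else factor(trials[[vary_by]])
  glev <- levels(groups)
  ng_cells <- length(glev)
  ng <- if (vary_param == "none") 1L else ng_cells

  if (!is.null(drift_by)) {
    lev <- factor(ifelse(trials$signal == 1,
                         as.character(trials[[drift_by]]), "noise"))
  } else {
    lev <- factor(ifelse(trials$signal == 1, "signal", "noise"))
  }
  vlev <- levels(lev)

  # --- observed bins per cell ------------------------------------------
  cells <- list()
  for (g in glev) for (l in vlev) {
    idx <- which(groups == g & lev == l)
    if (!length(idx)) next
    tr <- trials[idx, , drop = FALSE]
    yes <- tr$choice == 1 & is.finite(tr$rt)
    rts_up <- tr$rt[yes]
    edges_up <- if (sum(yes) >= length(quantile_probs) + 1)
      rt_quantiles(rts_up, quantile_probs) else numeric(0)
    counts_up <- bin_counts(rts_up, edges_up)
    if (task == "yesno") {
      no <- tr$choice == 0 & is.finite(tr$rt)
      rts_lo <- tr$rt[no]
      edges_lo <- if (sum(no) >= length(quantile_probs) + 1)
        rt_quantiles(rts_lo, quantile_probs) else numeric(0)
      counts_lo <- bin_counts(rts_lo, edges_lo)
      obs <- c(counts_up, counts_lo)
      collapsed <- FALSE
    } else {
      edges_lo <- numeric(0)
      obs <- c(counts_up, sum(tr$choice == 0, na.rm = TRUE))
      collapsed <- TRUE
    }
    cells[[length(cells) + 1]] <- list(
      group = g, level = l, n = nrow(tr),
      sign = if (l == "noise" && is.null(drift_by)) -1 else 1,
      edges_up = edges_up, edges_lo = edges_lo,
      observed = obs, collapsed = collapsed,
      sim_seed = derive_seed(seed, length(cells) + 101L))
  }
  n_total <- sum(vapply(cells, `[[`, 0, "n"))
  min_rt <- suppressWarnings(min(trials$rt, na.rm = TRUE))
  if (!is.finite(min_rt)) stop("no finite RTs to fit")
  t0_max <- 0.98 * min_rt
  tau_hi <- min(10, 2 * suppressWarnings(max(trials$rt, na.rm = TRUE)))

  # --- parameter vector layout -----------------------------------------
  nv <- if (is.null(drift_by)) 1L else length(vlev)
  layout <- list()
  add <- function(name, len) layout[[name]] <<- len
  add("v", nv)
  add("a", 1L)
  add("t0", 1L)
  if (vary_param == "v_bias") add("v_bias", ng)
  else if (fit_vbias) add("v_bias", 1L)
  if (vary_param == "z_rel") add("z_rel", ng)
  else if (fit_z) add("z_rel", 1L)
  if (fit_sv) add("sv", 1L)
  if (vary_param == "tau") add("tau", ng)
  k <- sum(unlist(layout))
  offsets <- cumsum(c(0, unlist(layout)))[seq_along(layout)]
  names(offsets) <- names(layout)
  blk <- function(theta, name) {
    if (is.null(layout[[name]])) return(NULL)
    theta[offsets[[name]] + seq_len(layout[[name]])]
  }

  decode <- function(theta) {
    p <- list()
    p$v <- blk(theta, "v")
    p$a <- exp(blk(theta, "a"))
    p$t0 <- stats::plogis(blk(theta, "t0")) * t0_max
    p$v_bias <- if (!is.null(layout$v_bias)) blk(theta, "v_bias") else 0
    p$z_rel <- if (!is.null(layout$z_rel)) stats::plogis(blk(theta, "z_rel"))
               else rep(0.5, 1)
    p$sv <- if (fit_sv) exp(blk(theta, "sv")) else 0
    # bounded transform: a collapse later than the slowest observed
    # response is indistinguishable from a still-later one
    p$tau <- if (!is.null(layout$tau))
      0.05 + (tau_hi - 0.05) * stats::plogis(blk(theta, "tau")) else Inf
    p
  }

  gidx <- match(vapply(cells, `[[`, "", "group"), glev)
  lidx <- match(vapply(cells, `[[`, "", "level"), vlev)
  pick <- function(vec, i) if (length(vec) > 1) vec[i] else vec[1]

  objective <- function(theta) {
    p <- decode(theta)
    g <- 0
    for (ci in seq_along(cells)) {
      cell <- cells[[ci]]
      vdrift <- if (nv > 1) p$v[lidx[ci]] else cell$sign * p$v
      mu <- vdrift + pick(p$v_bias, gidx[ci])
      z <- pick(p$z_rel, gidx[ci])
      tau <- pick(p$tau, gidx[ci])
      ep <- if (is.infinite(tau)) {
        cpp_expected_probs(mu, p$sv, p$a, z, p$t0, s,
                           cell$edges_up, cell$edges_lo, cell$collapsed)
      } else {
        cpp_expected_probs_sim(mu, p$sv, p$a, z, p$t0, tau, s, dt_sim,
                               cell$edges_up, cell$edges_lo, cell$collapsed,
                               as.integer(n_sim), cell$sim_seed)
      }
      g <- g + cpp_gsq(cell$observed, ep)
    }
    if (!is.finite(g)) 1e12 else g
  }

  # --- multi-start optimization ----------------------------------------
  start0 <- numeric(k)
  start0[offsets[["v"]] + seq_len(nv)] <- 1
  if (nv > 1 && "noise" %in% vlev)
    start0[offsets[["v"]] + match("noise", vlev)] <- -1
  start0[offsets[["a"]] + 1] <- log(1)
  start0[offsets[["t0"]] + 1] <- stats::qlogis(min(0.6 * min_rt, t0_max * 0.9) / t0_max)
  if (fit_sv) start0[offsets[["sv"]] + 1] <- log(0.3)
  if (!is.null(layout$tau))
    start0[offsets[["tau"]] + seq_len(layout$tau)] <-
      stats::qlogis((1.5 - 0.05) / 9.95)
  has_sim_cells <- !is.null(layout$tau)
  if (is.null(maxit))
    maxit <- if (has_sim_cells) 150L * k else 400L * k

  set.seed(derive_seed(seed, 1L))
  best <- NULL
  conv <- FALSE
  for (st in seq_len(n_starts)) {
    th <- if (st == 1) start0 else start0 + rnorm(k, sd = 0.4)
    fit <- optim(th, objective, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = 1e-7))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish the best solution
  fit <- optim(best$par, objective, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-8))
  if (fit$value <= best$value) best <- fit
  conv <- best$convergence == 0
  if (!conv)
    warning("optimizer did not fully converge; returning best-so-far")

  p <- decode(best$par)
  vnames <- if (nv > 1) vlev else NULL
  params <- list(
    v = setNames(p$v, vnames),
    v_bias = if (length(p$v_bias) > 1) setNames(p$v_bias, glev) else p$v_bias,
    z_rel = if (length(p$z_rel) > 1) setNames(p$z_rel, glev) else p$z_rel,
    a = p$a, t0 = p$t0, sv = if (fit_sv) p$sv else 0, s = s,
    tau_urgency = if (length(p$tau) > 1) setNames(p$tau, glev) else p$tau)

  expected <- lapply(seq_along(cells), function(ci) {
    cell <- cells[[ci]]
    vdrift <- if (nv > 1) p$v[lidx[ci]] else cell$sign * p$v
    mu <- vdrift + pick(p$v_bias, gidx[ci])
    z <- pick(p$z_rel, gidx[ci])
    tau <- pick(p$tau, gidx[ci])
    ep <- if (is.infinite(tau))
      cpp_expected_probs(mu, p$sv, p$a, z, p$t0, s,
                         cell$edges_up, cell$edges_lo, cell$collapsed)
    else
      cpp_expected_probs_sim(mu, p$sv, p$a, z, p$t0, tau, s, dt_sim,
                             cell$edges_up, cell$edges_lo, cell$collapsed,
                             as.integer(n_sim), cell$sim_seed)
    cell$n * ep
  })

  structure(list(params = params, gsq = best$value, n_trials = n_total,
                 k_params = k, bic = best$value + k * log(n_total),
                 observed = lapply(cells, `[[`, "observed"),
                 expected = expected,
                 cells = lapply(cells, function(cc)
                   cc[c("group", "level", "n")]),
                 converged = conv),
            class = "ddm_fit")
}

# counts per inter-quantile bin (length(edges) + 1 bins); empty edges
# collapse everything into one bin
bin_counts <- function(rts, edges) {
  if (!length(edges)) return(length(rts))
  b <- findInterval(rts, edges, left.open = TRUE) + 1L
  tabulate(b, nbins = length(edges) + 1L)
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("Quantile G-square diffusion fit\n")
  cat("  n =", x$n_trials, " k =", x$k_params,
      " G2 =", signif(x$gsq, 5), " BIC =", signif(x$bic, 6), "\n")
  for (nm in c("v", "v_bias", "z_rel", "a", "t0", "sv", "tau_urgency")) {
    val <- x$params[[nm]]
    cat("  ", format(nm, width = 11), ":",
        paste(signif(val, 4), collapse = ", "), "\n")
  }
  if (!x$converged) cat("  (not fully converged)\n")
  invisible(x)
}

#' Compare fits by BIC
#'
#' Ranks quantile G-square fits of the same data by BIC
#' (`G^2 + k log n`, the deviance convention used throughout); differences
#' below 2 are reported as ties.
#'
#' @param ... named `ddm_fit` objects, or a single named list of them.
#' @return data.frame with `model`, `gsq`, `k`, `bic`, `delta_bic`,
#'   `tie` columns, ordered best first.
#' @export
bic_compare <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "ddm_fit")) fits <- fits[[1]]
  stopifnot(all(vapply(fits, inherits, TRUE, "ddm_fit")))
  ns <- vapply(fits, `[[`, 0, "n_trials")
  if (length(unique(ns)) != 1)
    stop("fits must be on identical data (mismatched n)")
  out <- data.frame(model = names(fits),
                    gsq = vapply(fits, `[[`, 0, "gsq"),
                    k = vapply(fits, `[[`, 0, "k_params"),
                    bic = vapply(fits, `[[`, 0, "bic"))
  out <- out[order(out$bic), ]
  out$delta_bic <- out$bic - out$bic[1]
  out$tie <- out$delta_bic < 2
  rownames(out) <- NULL
  out
}

#' Forward-predict behavioral metrics from fitted parameters
#'
#' Simulates a large trial set (default 100K) from a parameter set while
#' matching the empirical signal/noise composition, then computes RT,
#' sensitivity (d') and choice bias per the signal-detection module --
#' the model-prediction overlays plotted against empirical per-bin
#' metrics.
#'
#' @param params a [ddm_params()] object.
#' @param n_trials simulated trials (default 1e5).
#' @param frac_signal fraction of signal trials.
#' @param loudness_mix optional named vector of signal-trial proportions
#'   per loudness level (go/no-go composite-bias route).
#' @param seed,dt simulator controls.
#' @return list with `rt_median`, `rt_mean`, `p_yes`, `d_prime`,
#'   `criterion`, and `overall_bias` (composite statistic when a loudness
#'   mix is given, otherwise equal to `criterion`).
#' @export
predict_behavior_metrics <- function(params, n_trials = 1e5,
                                     frac_signal = 0.5,
                                     loudness_mix = NULL, seed = 1,
                                     dt = 0.001) {
  n_sig <- round(n_trials * frac_signal)
  signal <- c(rep(1L, n_sig), rep(0L, n_trials - n_sig))
  loud <- NULL
  if (!is.null(loudness_mix)) {
    mix <- loudness_mix / sum(loudness_mix)
    loud <- rep(NA_character_, n_trials)
    loud[seq_len(n_sig)] <- rep(names(mix),
                                length.out = n_sig)[order(runif(n_sig))]
  }
  sim <- simulate_ddm(params, signal = signal, loudness = loud,
                      seed = seed, dt = dt)
  yes <- sim$choice == 1
  hit <- yes & signal == 1
  fa <- yes & signal == 0
  m <- sdt_d_prime_criterion(sum(hit, na.rm = TRUE),
                             sum(!yes & signal == 1, na.rm = TRUE),
                             sum(fa, na.rm = TRUE),
                             sum(!yes & signal == 0, na.rm = TRUE))
  ob <- m$criterion
  if (!is.null(loudness_mix)) {
    per <- lapply(names(loudness_mix), function(l) {
      sl <- signal == 1 & loud == l
      sdt_d_prime_criterion(sum(yes & sl, na.rm = TRUE),
                            sum(!yes & sl, na.rm = TRUE),
                            sum(fa, na.rm = TRUE),
                            sum(!yes & signal == 0, na.rm = TRUE))
    })
    names(per) <- names(loudness_mix)
    cb <- try(composite_overall_bias(per), silent = TRUE)
    if (!inherits(cb, "try-error")) ob <- cb$overall_bias
  }
  list(rt_median = median(sim$rt, na.rm = TRUE),
       rt_mean = mean(sim$rt, na.rm = TRUE),
       p_yes = mean(yes, na.rm = TRUE),
       d_prime = m$d_prime, criterion = m$criterion,
       overall_bias = ob)
}
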