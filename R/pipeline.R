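#' Default end-to-end pipeline configuration
#'
#' Bundles the stage specifications: task design, generative diffusion
#' parameters, arousal coupling, preprocessing constants and group-stats
#' options. Every field can be overridden.
#'
#' @param task a [task_spec()].
#' @param params generative [ddm_params()].
#' @param coupling an [arousal_coupling_spec()].
#' @param preproc a [preproc_config()].
#' @param bias_base per-subject baseline drift biases (recycled).
#' @param fit_ddm also run per-subject bin-varying drift-bias fits
#'   (slower; default `FALSE`).
#' @param seed master seed, fanned out to per-stage substreams.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(task = task_spec("gonogo", n_subjects = 12),
                            params = NULL,
                            coupling = arousal_coupling_spec(),
                            preproc = NULL,
                            bias_base = -0.5,
                            fit_ddm = FALSE,
                            seed = 1) {
  if (is.null(params)) {
    v <- if (task$task_kind == "gonogo")
      setNames(seq(0.6, 2.6, length.out = length(task$loudness_levels)),
               as.character(task$loudness_levels))
    else 1
    if (task$task_kind == "gonogo") v <- c(v, noise = -1)
    params <- ddm_params(v = v, v_bias = bias_base[1], a = 1.2,
                         t0 = 0.35)
  }
  if (is.null(preproc))
    preproc <- preproc_config(species = task$species,
                              task_kind = task$task_kind)
  structure(list(task = task, params = params, coupling = coupling,
                 preproc = preproc,
                 bias_base = rep(bias_base,
                                 length.out = task$n_subjects),
                 fit_ddm = fit_ddm, seed = seed),
            class = "pipeline_config")
}

#' Run the end-to-end analysis pipeline
#'
#' simulate -> preprocess -> bin -> signal-detection metrics per bin ->
#' (optional per-subject diffusion fits) -> group statistics. Fully
#' deterministic under a fixed seed. For go/no-go data the per-bin bias
#' metric is the composite overall bias (one false-alarm rate, multiple
#' hit rates); for yes/no data it is the criterion.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with `dataset`, `trials`
#'   (augmented, all subjects), `bin_metrics` (subject x bin bias, d',
#'   RT), `group_fit` (a `seq_poly_fit` on bias vs bin), `ddm_fits`
#'   (optional), `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  ds <- generate_dataset(config$task, config$params, config$coupling,
                         bias_base = config$bias_base,
                         seed = derive_seed(config$seed, 1L))
  gonogo <- config$task$task_kind == "gonogo"
  aug <- list()
  for (s in seq_len(config$task$n_subjects)) {
    tr <- ds$trials[ds$trials$subject_id == s, ]
    pp <- preprocess_subject(ds$traces[[s]], tr, config$preproc,
                             stratify_by = if (gonogo) "loudness_db"
                                           else NULL)
    aug[[s]] <- pp$trials
  }
  trials <- do.call(rbind, aug)

  bm <- list()
  for (s in seq_len(config$task$n_subjects)) {
    tr <- trials[trials$subject_id == s & !is.na(trials$pupil_bin), ]
    for (b in sort(unique(tr$pupil_bin))) {
      tb <- tr[tr$pupil_bin == b, ]
      met <- tryCatch(
        bin_bias_metrics(tb, gonogo), error = function(e) NULL)
      if (is.null(met)) next
      bm[[length(bm) + 1]] <- data.frame(
        subject = s, bin = b, bias = met$bias, d_prime = met$d_prime,
        rt = median(tb$rt_s, na.rm = TRUE))
    }
  }
  bin_metrics <- do.call(rbind, bm)

  gdat <- data.frame(subject = bin_metrics$subject,
                     y = bin_metrics$bias, P = bin_metrics$bin)
  group_fit <- fit_sequential_polynomial(gdat, use_loudness = FALSE)

  ddm_fits <- NULL
  if (config$fit_ddm) {
    ddm_fits <- lapply(seq_len(config$task$n_subjects), function(s) {
      tr <- trials[trials$subject_id == s & !is.na(trials$pupil_bin), ]
      dat <- data.frame(choice = tr$choice,
                        rt = if (gonogo) tr$rt_s else tr$rt_s,
                        signal = tr$signal_present,
                        pupil_bin = tr$pupil_bin)
      fit_ddm_quantile(dat, task = if (gonogo) "gonogo" else "yesno",
                       vary_param = "v_bias", vary_by = "pupil_bin",
                       fit_sv = FALSE, n_starts = 3,
                       seed = derive_seed(config$seed, 80L + s))
    })
  }
  structure(list(dataset = ds, trials = trials,
                 bin_metrics = bin_metrics, group_fit = group_fit,
                 ddm_fits = ddm_fits, config = config),
            class = "pipeline_result")
}

# per-bin bias/sensitivity: composite overall bias for go/no-go (shared
# FAR, hit rate per loudness), criterion for yes/no
bin_bias_metrics <- function(tb, gonogo) {
  if (gonogo) {
    noise <- tb[tb$signal_present == 0, ]
    n_fa <- sum(noise$choice == 1, na.rm = TRUE)
    n_cr <- sum(noise$choice == 0, na.rm = TRUE)
    louds <- sort(unique(tb$loudness_db[tb$signal_present == 1]))
    per <- lapply(louds, function(l) {
      sl <- tb$signal_present == 1 & tb$loudness_db == l
      sdt_d_prime_criterion(sum(tb$choice[sl] == 1, na.rm = TRUE),
                            sum(tb$choice[sl] == 0, na.rm = TRUE),
                            n_fa, n_cr)
    })
    cb <- composite_overall_bias(per)
    list(bias = cb$overall_bias,
         d_prime = mean(vapply(per, `[[`, 0, "d_prime")))
  } else {
    m <- sdt_d_prime_criterion(
      sum(tb$choice == 1 & tb$signal_present == 1, na.rm = TRUE),
      sum(tb$choice == 0 & tb$signal_present == 1, na.rm = TRUE),
      sum(tb$choice == 1 & tb$signal_present == 0, na.rm = TRUE),
      sum(tb$choice == 0 & tb$signal_present == 0, na.rm = TRUE))
    list(bias = m$criterion, d_prime = m$d_prime)
  }
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pupil-arousal decision-bias pipeline\n")
  cat(sprintf("  %d subjects, %d analyzed trials, task %s\n",
              x$config$task$n_subjects, nrow(x$trials),
              x$config$task$task_kind))
  agg <- aggregate(bias ~ bin, data = x$bin_metrics, FUN = mean)
  cat("  group-mean bias by arousal bin:\n")
  print(round(setNames(agg$bias, paste0("bin", agg$bin)), 4))
  cat("  selected pupil dependence:", x$group_fit$order, "\n")
  invisible(x)
}

#' Render summary figures for a pipeline result
#'
#' Per-bin bias and sensitivity with the selected polynomial overlay,
#' and (when per-subject diffusion fits are present) fitted drift bias
#' per bin. Missing stages are skipped gracefully.
#'
#' @param result a `pipeline_result`.
#' @param file optional PDF path; plots are returned invisibly either
#'   way.
#' @return named list of ggplot objects.
#' @export
render_report <- function(result, file = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  bm <- result$bin_metrics
  agg <- aggregate(cbind(bias, d_prime, rt) ~ bin, data = bm,
                   FUN = mean)
  plots <- list()
  p_bias <- ggplot2::ggplot(agg, ggplot2::aes(x = bin, y = bias)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "arousal bin", y = "choice bias",
                  title = "Choice bias by phasic-arousal bin") +
    ggplot2::theme_minimal()
  ord <- result$group_fit$order
  if (ord == "linear")
    p_bias <- p_bias + ggplot2::geom_smooth(method = "lm",
                                            formula = y ~ x, se = FALSE)
  if (ord == "quadratic")
    p_bias <- p_bias + ggplot2::geom_smooth(method = "lm",
                                            formula = y ~ x + I(x^2),
                                            se = FALSE)
  plots$bias <- p_bias
  plots$d_prime <- ggplot2::ggplot(agg,
                                   ggplot2::aes(x = bin, y = d_prime)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "arousal bin", y = "d'",
                  title = "Sensitivity by phasic-arousal bin") +
    ggplot2::theme_minimal()
  if (!is.null(result$ddm_fits)) {
    vb <- do.call(rbind, lapply(seq_along(result$ddm_fits),
      function(s) {
        v <- result$ddm_fits[[s]]$params$v_bias
        data.frame(subject = s, bin = as.numeric(names(v)),
                   v_bias = unname(v))
      }))
    aggv <- aggregate(v_bias ~ bin, data = vb, FUN = mean)
    plots$drift_bias <- ggplot2::ggplot(
      aggv, ggplot2::aes(x = bin, y = v_bias)) +
      ggplot2::geom_point(size = 2, colour = "red") +
      ggplot2::labs(x = "arousal bin", y = "fitted drift bias",
                    title = "Drift bias by phasic-arousal bin") +
      ggplot2::theme_minimal()
  }
  if (!is.null(file)) {
    grDevices::pdf(file, width = 5, height = 4)
    for (p in plots) print(p)
    grDevices::dev.off()
  }
  invisible(plots)
}
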