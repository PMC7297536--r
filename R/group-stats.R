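#' Sequential polynomial mixed-model selection
#'
#' Quantifies how a behavioral metric depends on arousal bin by fitting a
#' nested ladder of linear mixed models -- constant
#' (`y ~ 1 (+ S)`), first-order (`... + P`) and second-order
#' (`... + P + P^2`), with `S` the signal loudness (go/no-go only) and
#' `P` the pupil-bin number -- and stepping up an order only while BIC
#' improves. Random effects use the maximal structure justified by the
#' design (by-subject intercepts plus `S` and `P` slopes), falling back
#' to random intercepts only if the maximal fit fails or is singular.
#' The winning model is refitted by REML. The quadratic term enters as a
#' fixed effect only.
#'
#' @param data data.frame with columns `subject`, `y`, `P`, optionally
#'   `S`.
#' @param use_loudness include the `S` predictor.
#' @return list of class `seq_poly_fit`: `order` (`"constant"`,
#'   `"linear"`, `"quadratic"`), `coefficients` (fixed effects, with
#'   standard errors), `bic` (per candidate), `model` (the REML refit),
#'   `fallback` (logical, random-intercept fallback used).
#' @export
fit_sequential_polynomial <- function(data, use_loudness = "S" %in%
                                        names(data)) {
  stopifnot(all(c("subject", "y", "P") %in% names(data)))
  if (length(unique(data$P)) < 2) stop("need >= 2 bins")
  if (length(unique(data$subject)) < 2) stop("need >= 2 subjects")
  data$subject <- factor(data$subject)
  data$P2 <- data$P^2
  fixed <- c(constant = "y ~ 1", linear = "y ~ 1 + P",
             quadratic = "y ~ 1 + P + P2")
  if (use_loudness)
    fixed <- vapply(fixed, function(f) sub("1", "1 + S", f), "")
  re_max <- if (use_loudness) "(1 + S + P | subject)"
            else "(1 + P | subject)"
  re_min <- "(1 | subject)"
  fit_one <- function(f, reml) {
    for (re in c(re_max, re_min)) {
      m <- tryCatch(
        suppressWarnings(suppressMessages(
          lme4::lmer(as.formula(paste(f, "+", re)), data = data,
                     REML = reml,
                     control = lme4::lmerControl(
                       check.conv.singular = "ignore")))),
        error = function(e) NULL)
      if (!is.null(m)) return(list(m = m, fallback = re == re_min))
    }
    NULL
  }
  if (sd(data$y) < 1e-10) {
    # degenerate: a perfectly flat metric carries no pupil dependence,
    # and mixed models cannot be fit to zero-variance data
    co <- matrix(c(mean(data$y), 0, NA), 1, 3,
                 dimnames = list("(Intercept)",
                                 c("Estimate", "Std. Error", "t value")))
    return(structure(list(order = "constant", coefficients = co,
                          bic = c(constant = NA_real_,
                                  linear = NA_real_,
                                  quadratic = NA_real_),
                          model = NULL, fallback = TRUE),
                     class = "seq_poly_fit"))
  }
  fits <- lapply(fixed, fit_one, reml = FALSE)
  bic <- vapply(fits, function(f) if (is.null(f)) Inf else BIC(f$m), 0)
  # serial hierarchy: each higher order must beat the current winner
  sel <- 1L
  for (k in 2:length(bic)) if (bic[k] < bic[sel]) sel <- k
  order <- names(fixed)[sel]
  refit <- fit_one(fixed[[sel]], reml = TRUE)
  sm <- summary(refit$m)$coefficients
  structure(list(order = order,
                 coefficients = sm,
                 bic = setNames(bic, names(fixed)),
                 model = refit$m, fallback = refit$fallback),
            class = "seq_poly_fit")
}

#' @export
print.seq_poly_fit <- function(x, ...) {
  cat("Sequential polynomial mixed-model selection\n")
  cat("  selected order:", x$order, "\n")
  cat("  BIC:", paste(sprintf("%s=%.1f", names(x$bic), x$bic),
                      collapse = "  "), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Cluster-corrected one-sample permutation test on a time course
#'
#' Pointwise one-sample t-tests across subjects; contiguous runs of
#' samples with `|t|` above the two-sided alpha threshold form clusters
#' whose mass (sum of t within the cluster) is compared to a null built
#' by random sign flips of whole subjects (the maximal absolute cluster
#' mass per permutation). Clusters with permutation p below alpha are
#' significant.
#'
#' @param mat subjects x time matrix.
#' @param times optional time axis (seconds).
#' @param alpha cluster-forming and reporting threshold.
#' @param n_perm number of sign-flip permutations (>= 100).
#' @param seed RNG seed.
#' @return list of class `cluster_test`: `clusters` data.frame
#'   (`start`, `end`, `start_s`, `end_s`, `mass`, `p`), `t` pointwise
#'   statistics, `threshold`, `alpha`, `significant` (clusters with
#'   `p < alpha`).
#' @export
cluster_permutation_timecourse <- function(mat, times = NULL,
                                           alpha = 0.05, n_perm = 10000,
                                           seed = 1) {
  mat <- as.matrix(mat)
  n <- nrow(mat); m <- ncol(mat)
  if (n < 5) stop("need >= 5 subjects")
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (is.null(times)) times <- seq_len(m)
  thr <- qt(1 - alpha / 2, df = n - 1)
  sumsq <- colSums(mat^2)
  tstat_of <- function(means) {
    s2 <- (sumsq - n * means^2) / (n - 1)
    s2[s2 < 1e-300] <- 1e-300
    means / sqrt(s2 / n)
  }
  tobs <- tstat_of(colMeans(mat))
  clusters_of <- function(tv) {
    # contiguous supra-threshold runs of common sign
    supra <- abs(tv) > thr
    if (!any(supra)) return(NULL)
    idx <- which(supra)
    brk <- c(TRUE, diff(idx) > 1 | sign(tv[idx[-1]]) !=
               sign(tv[idx[-length(idx)]]))
    grp <- cumsum(brk)
    do.call(rbind, lapply(split(idx, grp), function(ii)
      data.frame(start = min(ii), end = max(ii),
                 mass = sum(tv[ii]))))
  }
  obs <- clusters_of(tobs)
  # null: maximal absolute cluster mass per sign-flip permutation
  max_mass <- function(tv) {
    supra <- abs(tv) > thr
    if (!any(supra)) return(0)
    idx <- which(supra)
    brk <- cumsum(c(1L, (diff(idx) > 1L) |
                      (sign(tv[idx[-1]]) != sign(tv[idx[-length(idx)]]))))
    max(abs(rowsum(tv[idx], brk)))
  }
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                  n_perm, n)
  perm_means <- (signs %*% mat) / n
  null_max <- vapply(seq_len(n_perm), function(i)
    max_mass(tstat_of(perm_means[i, ])), 0)
  if (is.null(obs)) {
    cl <- data.frame(start = integer(), end = integer(),
                     start_s = numeric(), end_s = numeric(),
                     mass = numeric(), p = numeric())
  } else {
    cl <- obs
    cl$start_s <- times[cl$start]
    cl$end_s <- times[cl$end]
    cl$p <- vapply(cl$mass, function(mm)
      (1 + sum(null_max >= abs(mm))) / (1 + n_perm), 0)
    cl <- cl[, c("start", "end", "start_s", "end_s", "mass", "p")]
    rownames(cl) <- NULL
  }
  structure(list(clusters = cl, t = tobs, threshold = thr,
                 alpha = alpha,
                 significant = cl[cl$p < alpha, , drop = FALSE]),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat("Cluster-corrected one-sample permutation test\n")
  cat(sprintf("  threshold |t| > %.3f (alpha = %g)\n", x$threshold,
              x$alpha))
  if (nrow(x$clusters) == 0) cat("  no clusters\n")
  else print(round(x$clusters, 4))
  invisible(x)
}

#' Paired tests and bootstrap correlations
#'
#' `kind = "paired_t"` runs a paired-sample t-test on `x - y`.
#' `kind = "pearson_bootstrap"` computes Pearson's r with a percentile
#' bootstrap confidence interval (default level 0.60, the convention for
#' the individual-differences scatter plots).
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @param kind test kind.
#' @param conf_level bootstrap CI level.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed.
#' @return list with `statistic` and `p_value` (paired t) or `r` and
#'   `ci` (bootstrap correlation).
#' @export
association_tests <- function(x, y, kind = c("paired_t",
                                             "pearson_bootstrap"),
                              conf_level = 0.60, n_boot = 5000,
                              seed = 1) {
  kind <- match.arg(kind)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (kind == "paired_t") {
    d <- x - y
    if (sd(d) == 0) stop("zero variance in differences; t undefined")
    tt <- t.test(x, y, paired = TRUE)
    return(list(statistic = unname(tt$statistic),
                p_value = tt$p.value,
                mean_difference = unname(tt$estimate)))
  }
  r <- cor(x, y)
  set.seed(seed)
  n <- length(x)
  rb <- vapply(seq_len(n_boot), function(i) {
    ii <- sample.int(n, n, replace = TRUE)
    if (sd(x[ii]) == 0 || sd(y[ii]) == 0) return(NA_real_)
    cor(x[ii], y[ii])
  }, 0)
  ci <- quantile(rb, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                 na.rm = TRUE, names = FALSE)
  list(r = r, ci = ci, conf_level = conf_level)
}
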