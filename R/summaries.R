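#' Equal-tail credible interval
#'
#' Empirical quantiles at `(1-level)/2` and `1-(1-level)/2`, using linear
#' interpolation between order statistics (the type-7 convention; stated
#' explicitly because tail quantiles of moderately sized samples are
#' convention-sensitive).
#'
#' @param samples Numeric vector of draws (>= 2 finite values).
#' @param level Interval mass in (0, 1]; `level = 1` gives the range.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
equal_tail_ci <- function(samples, level = 0.95) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 2) stop("need at least 2 finite samples")
  if (!(level > 0 && level <= 1)) stop("level must lie in (0, 1]")
  a <- (1 - level) / 2
  q <- stats::quantile(samples, c(a, 1 - a), type = 7, names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Posterior mode from draws
#'
#' Argmax of a Gaussian kernel density estimate (Silverman's rule-of-thumb
#' bandwidth) evaluated on a regular grid spanning the sample range, so a
#' mode pinned at a boundary is representable. With fewer than 30 draws
#' the sample median is returned with a warning.
#'
#' @param samples Numeric vector of draws.
#' @param n_grid Grid resolution (default 512).
#' @param bw Bandwidth rule passed to [stats::density()].
#' @return The estimated mode (scalar).
#' @export
posterior_mode <- function(samples, n_grid = 512, bw = "nrd0") {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 30) {
    warning("fewer than 30 draws; returning the median instead of a KDE mode")
    return(stats::median(samples))
  }
  if (max(samples) == min(samples)) {
    return(samples[1])
  }
  d <- stats::density(samples, bw = bw, n = n_grid, from = min(samples), to = max(samples))
  d$x[which.max(d$y)]
}

#' Effective sample size and Monte-Carlo standard error
#'
#' `ess()` estimates the effective number of independent draws from the
#' autocorrelation function, truncated at the first lag whose estimated
#' autocorrelation drops below 0.05 (or turns negative). `mcse()` is
#' `sd(x)/sqrt(ess(x))`.
#'
#' @param x Numeric vector of draws from one chain (or pooled draws).
#' @return A scalar.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) {
    return(n)
  }
  acf_est <- stats::acf(x, lag.max = min(n - 1, 500), plot = FALSE)$acf[-1]
  keep <- which(acf_est < 0.05)
  upto <- if (length(keep)) keep[1] - 1L else length(acf_est)
  denom <- 1 + 2 * sum(acf_est[seq_len(upto)])
  max(1, n / max(denom, 1))
}

#' @rdname ess
#' @export
mcse <- function(x) {
  stats::sd(x) / sqrt(ess(x))
}

#' Intraclass correlation for the random-intercept logistic model
#'
#' Latent-variable form: the binary outcome is seen as a thresholded
#' continuous variable whose residual follows a standard logistic
#' distribution (variance pi^2/3), giving
#' `ICC = sigma_u^2 / (sigma_u^2 + pi^2/3)`.
#'
#' @param sigma_u2 Between-cluster variance(s), >= 0 (vectorized).
#' @return ICC value(s) in \[0, 1).
#' @export
icc_logistic <- function(sigma_u2) {
  if (any(sigma_u2 < 0)) stop("sigma_u2 must be non-negative")
  sigma_u2 / (sigma_u2 + pi^2 / 3)
}

#' Intraclass correlation for the random-intercept log-binomial model
#'
#' The same latent-variable construction with a log link leads to a
#' residual following a unit-mean exponential distribution (variance 1),
#' giving `ICC = sigma_u^2 / (sigma_u^2 + 1)`. Applied draw-wise to
#' posterior samples of `sigma_u^2` it yields a posterior for the ICC.
#'
#' @inheritParams icc_logistic
#' @return ICC value(s) in \[0, 1).
#' @export
icc_logbinomial <- function(sigma_u2) {
  if (any(sigma_u2 < 0)) stop("sigma_u2 must be non-negative")
  sigma_u2 / (sigma_u2 + 1)
}

#' Relative difference in percent between point estimates
#'
#' `100 * (est - ref) / |ref|`: the signed percentage difference of an
#' estimate from a reference method's estimate.
#'
#' @param est,ref Point estimates; `ref` must be nonzero.
#' @return Percentage (vectorized over `est`).
#' @export
pct_rel_diff <- function(est, ref) {
  if (any(ref == 0)) stop("reference estimate must be nonzero")
  100 * (est - ref) / abs(ref)
}

#' Width of an interval
#'
#' @param lower,upper Interval endpoints with `upper >= lower`.
#' @return `upper - lower`.
#' @export
ci_range <- function(lower, upper) {
  if (any(upper < lower)) stop("inverted interval: upper < lower")
  upper - lower
}

#' Summarize an MCMC run
#'
#' Pools the retained draws of all chains and reports, per parameter, the
#' KDE posterior mode and the equal-tail credible interval. Parameters
#' listed in `ratio_for` are additionally summarized on the ratio scale:
#' the draws are exponentiated first and the mode/interval computed on
#' the transformed draws (the interval therefore equals the exponentiated
#' coefficient-scale interval, while the mode does not, because a KDE
#' mode does not commute with a nonlinear transform). For mixed models a
#' block with the random-effect variance and the log-binomial ICC
#' (draw-wise transform of `sigma_u^2`) is appended.
#'
#' @param chains An `rr_chains` object from [run_chains()].
#' @param ratio_for Character vector of parameter names to report as
#'   ratios (RR/PR); defaults to all regression coefficients except the
#'   intercept(s).
#' @param level Credible level (default 0.95).
#' @param rhat_warn Warn when any R-hat exceeds this threshold.
#' @return A data.frame of class `"rr_summary"` with columns `parameter`,
#'   `scale` (`"coefficient"`, `"ratio"` or `"derived"`), `mode`, `lower`,
#'   `upper`, `level`.
#' @export
summarize_chains <- function(chains, ratio_for = NULL, level = 0.95, rhat_warn = 1.1) {
  stopifnot(inherits(chains, "rr_chains"))
  if (any(chains$rhat > rhat_warn)) {
    warning(
      "Gelman-Rubin R-hat exceeds ", rhat_warn, " for: ",
      paste(names(chains$rhat)[chains$rhat > rhat_warn], collapse = ", ")
    )
  }
  pooled <- pooled_draws(chains)
  if (is.null(ratio_for)) {
    cand <- grep("^u\\[|^sigma_u$", chains$coef_names, invert = TRUE, value = TRUE)
    ratio_for <- grep("Intercept", cand, invert = TRUE, value = TRUE)
  }
  if (!all(ratio_for %in% colnames(pooled))) {
    stop(
      "unknown parameter name(s): ",
      paste(setdiff(ratio_for, colnames(pooled)), collapse = ", ")
    )
  }
  report <- setdiff(colnames(pooled), grep("^u\\[", colnames(pooled), value = TRUE))
  rows <- lapply(report, function(p) {
    ci <- equal_tail_ci(pooled[, p], level)
    data.frame(
      parameter = p, scale = if (p == "sigma_u") "derived" else "coefficient",
      mode = posterior_mode(pooled[, p]), lower = ci[1], upper = ci[2],
      level = level, stringsAsFactors = FALSE
    )
  })
  ratio_rows <- lapply(ratio_for, function(p) {
    ed <- exp(pooled[, p])
    ci <- equal_tail_ci(ed, level)
    data.frame(
      parameter = paste0(p, " RR"), scale = "ratio",
      mode = posterior_mode(ed), lower = ci[1], upper = ci[2],
      level = level, stringsAsFactors = FALSE
    )
  })
  derived <- list()
  if ("sigma_u" %in% colnames(pooled)) {
    s2 <- pooled[, "sigma_u"]^2
    ci_s2 <- equal_tail_ci(s2, level)
    icc <- icc_logbinomial(s2)
    ci_icc <- equal_tail_ci(icc, level)
    derived <- list(
      data.frame(
        parameter = "sigma_u2", scale = "derived",
        mode = posterior_mode(s2), lower = ci_s2[1], upper = ci_s2[2],
        level = level, stringsAsFactors = FALSE
      ),
      data.frame(
        parameter = "ICC", scale = "derived",
        mode = posterior_mode(icc), lower = ci_icc[1], upper = ci_icc[2],
        level = level, stringsAsFactors = FALSE
      )
    )
  }
  out <- do.call(rbind, c(rows, ratio_rows, derived))
  rownames(out) <- NULL
  class(out) <- c("rr_summary", "data.frame")
  out
}

#' @export
print.rr_summary <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$mode <- round(df$mode, digits)
  df$interval <- sprintf(
    "(%s; %s)",
    format(round(df$lower, digits), trim = TRUE),
    format(round(df$upper, digits), trim = TRUE)
  )
  print(df[, c("parameter", "scale", "mode", "interval")], row.names = FALSE)
  invisible(x)
}

#' Method-comparison table
#'
#' Aligns two or more summary tables (Bayesian or frequentist, in the
#' `rr_summary` schema) on shared parameter names and appends the signed
#' percentage difference of each method's point estimate from a named
#' reference method, and each interval's width.
#'
#' @param ... Named `rr_summary`-schema data.frames (name = method label).
#' @param ref Name of the reference method (default: the first).
#' @return A data.frame with one row per parameter x method, columns
#'   `parameter`, `method`, `estimate`, `lower`, `upper`, `delta_pct`,
#'   `ci_range`.
#' @export
compare_methods <- function(..., ref = NULL) {
  fits <- list(...)
  if (length(fits) == 1 && is.null(names(fits)) &&
    is.list(fits[[1]]) && !is.data.frame(fits[[1]])) {
    fits <- fits[[1]]
  }
  if (length(fits) < 2) stop("need at least 2 summaries to compare")
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("method", seq_along(fits))
  }
  if (is.null(ref)) ref <- names(fits)[1]
  if (!ref %in% names(fits)) stop("unknown reference method: ", ref)
  shared <- Reduce(intersect, lapply(fits, function(f) f$parameter))
  if (!length(shared)) stop("the summaries share no parameter names")
  est_col <- function(f) if ("mode" %in% names(f)) f$mode else f$estimate
  ref_fit <- fits[[ref]]
  ref_est <- est_col(ref_fit)[match(shared, ref_fit$parameter)]
  out <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    i <- match(shared, f$parameter)
    est <- est_col(f)[i]
    data.frame(
      parameter = shared, method = nm, estimate = est,
      lower = f$lower[i], upper = f$upper[i],
      delta_pct = ifelse(ref_est == 0, NA_real_, 100 * (est - ref_est) / abs(ref_est)),
      ci_range = f$upper[i] - f$lower[i],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' ROC analysis of predicted probabilities
#'
#' Empirical ROC over every distinct score threshold (prediction positive
#' when `score >= threshold`), AUC by the trapezoid rule, and the optimal
#' cutoff maximizing Youden's J = sensitivity + specificity - 1, ties
#' broken toward the larger threshold.
#'
#' @param probabilities Numeric scores (e.g. fitted probabilities).
#' @param y Binary outcome vector of the same length.
#' @return List with `points` (data.frame: threshold, sensitivity,
#'   specificity), `auc` and `cutoff`.
#' @export
roc_analysis <- function(probabilities, y) {
  if (length(probabilities) != length(y)) stop("lengths differ")
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: outcome has a single class")
  thr <- c(-Inf, sort(unique(probabilities)), Inf)
  sens <- vapply(thr, function(t) sum(probabilities >= t & y == 1L) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(probabilities < t & y == 0L) / n0, numeric(1))
  points <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))
  cutoff <- max(thr[best][is.finite(thr[best])], thr[best][1])
  list(points = points, auc = auc, cutoff = cutoff)
}
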