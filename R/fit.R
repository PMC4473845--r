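#' Bayesian relative-risk regression by constrained MCMC
#'
#' The package's main fitting function. Chooses the model family from the
#' data -- log-binomial for a binary outcome, mixed-effects log-binomial
#' when cluster labels are present (normal random intercept per cluster),
#' log-multinomial for a polytomous outcome -- and samples the posterior
#' under the valid-probability restriction (`theta_i <= 1` per row, and
#' for multinomial outcomes a non-negative reference-category
#' complement) with component-wise adaptive random-walk Metropolis.
#' Point estimates are posterior modes (KDE), intervals are equal-tail
#' credible intervals; ratio-scale (RR/PR) summaries are computed on the
#' exponentiated draws directly.
#'
#' @param data An [rr_data()] object (or an `rr_fixture` carrying one).
#' @param prior A [prior_spec()].
#' @param settings A [chain_settings()].
#' @param level Credible level for intervals.
#' @return An object of class `"rr_bayes"`: list with `chains` (the
#'   [run_chains()] result), `summary` (an `rr_summary` table), `data`,
#'   `prior`, `settings`, `level`.
#' @examples
#' \donttest{
#' d <- kerry_bland_trial()$data
#' fit <- rr_bayes(d, settings = chain_settings(
#'   n_chains = 2, n_iter = 1500, burn_in = 500, thin = 1, seed = 42
#' ))
#' summary(fit)
#' }
#' @export
rr_bayes <- function(data, prior = prior_spec(), settings = chain_settings(), level = 0.95) {
  if (inherits(data, "rr_fixture")) {
    if (is.null(data$data)) stop("fixture '", data$name, "' is aggregate-only; expand it first")
    data <- data$data
  }
  stopifnot(inherits(data, "rr_data"))
  chains <- run_chains(data, prior, settings)
  smry <- summarize_chains(chains, level = level)
  structure(
    list(
      chains = chains, summary = smry, data = data, prior = prior,
      settings = settings, level = level
    ),
    class = "rr_bayes"
  )
}

#' @export
print.rr_bayes <- function(x, ...) {
  model <- if (x$chains$family == "multinomial") {
    "log-multinomial"
  } else if (x$chains$mixed) "mixed-effects log-binomial" else "log-binomial"
  cat("Bayesian ", model, " model (constrained MCMC)\n", sep = "")
  cat(
    "  ", x$settings$n_chains, " chains x ", nrow(x$chains$draws[[1]]),
    " retained draws; max R-hat ", format(max(x$chains$rhat), digits = 4), "\n\n",
    sep = ""
  )
  print(x$summary, ...)
  invisible(x)
}

#' @export
summary.rr_bayes <- function(object, ...) object$summary

#' @export
coef.rr_bayes <- function(object, ...) {
  s <- object$summary
  cf <- s[s$scale == "coefficient", ]
  stats::setNames(cf$mode, cf$parameter)
}

#' @export
confint.rr_bayes <- function(object, parm, level = NULL, ...) {
  s <- if (is.null(level) || level == object$level) {
    object$summary
  } else {
    summarize_chains(object$chains, level = level)
  }
  ci <- as.matrix(s[, c("lower", "upper")])
  rownames(ci) <- s$parameter
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Predicted probabilities from the posterior
#'
#' Row probabilities at the posterior-mode coefficients
#' (`type = "mode"`), or the full matrix of per-draw probabilities
#' (`type = "draws"`). For mixed fits, prediction is at `u = 0` (a
#' typical cluster) unless `use_u = TRUE`, which uses the posterior modes
#' of the fitted cluster effects (only valid when `newdata` carries the
#' same clusters). Constrained-model predictions at the observed
#' covariates never exceed 1 at any retained draw; a mode-coefficient
#' prediction at new covariate rows can, and is then reported as-is.
#'
#' @param object An `rr_bayes` fit.
#' @param newdata An [rr_data()] (default: the training data).
#' @param type `"mode"` or `"draws"`.
#' @param use_u Use fitted cluster effects (mixed models only).
#' @param ... Unused.
#' @return A vector (binomial) or matrix (multinomial / draws).
#' @export
predict.rr_bayes <- function(object, newdata = NULL, type = c("mode", "draws"),
                             use_u = FALSE, ...) {
  type <- match.arg(type)
  data <- if (is.null(newdata)) object$data else newdata
  pooled <- pooled_draws(object$chains)
  cn <- colnames(object$data$x)
  if (object$chains$family == "multinomial") {
    get_B <- function(v) {
      matrix(v, nrow = object$data$J - 1L, ncol = length(cn), byrow = TRUE)
    }
    if (type == "mode") {
      modes <- vapply(object$chains$param_names, function(p) posterior_mode(pooled[, p]), numeric(1))
      return(rr_probabilities(get_B(modes), data))
    }
    stop("type = 'draws' is not implemented for multinomial fits")
  }
  u <- NULL
  if (use_u && object$chains$mixed) {
    unames <- grep("^u\\[", colnames(pooled), value = TRUE)
    u <- vapply(unames, function(p) posterior_mode(pooled[, p]), numeric(1))
  }
  if (type == "mode") {
    beta <- vapply(cn, function(p) posterior_mode(pooled[, p]), numeric(1))
    return(rr_probabilities(beta, data, u = u))
  }
  apply(pooled[, cn, drop = FALSE], 1, function(b) exp(linear_predictor(b, data, u = u)))
}

#' Trace plot of retained draws
#'
#' One panel per requested parameter, chains overlaid -- the standard
#' visual mixing check alongside the Gelman-Rubin statistic.
#'
#' @param x An `rr_bayes` fit.
#' @param parameters Parameter names (default: the regression coefficients).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.rr_bayes <- function(x, parameters = NULL, ...) {
  if (is.null(parameters)) parameters <- x$chains$coef_names
  old <- graphics::par(mfrow = c(length(parameters), 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (p in parameters) {
    m <- sapply(x$chains$draws, function(d) d[, p])
    graphics::matplot(m,
      type = "l", lty = 1, ylab = p,
      main = paste0(p, "  (R-hat ", format(x$chains$rhat[p], digits = 4), ")"), ...
    )
  }
  invisible(x)
}

#' Posterior-predictive simulation
#'
#' Draws outcome replicates: each simulation picks a retained posterior
#' draw and generates outcomes from the model at the observed covariates.
#'
#' @param object An `rr_bayes` fit (binomial families).
#' @param nsim Number of replicate outcome vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A matrix with `nsim` columns of simulated 0/1 outcomes.
#' @export
simulate.rr_bayes <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (object$chains$family == "multinomial") {
    stop("posterior-predictive simulation is implemented for binomial families")
  }
  pooled <- pooled_draws(object$chains)
  cn <- colnames(object$data$x)
  idx <- sample.int(nrow(pooled), nsim, replace = TRUE)
  out <- vapply(idx, function(i) {
    u <- if (object$chains$mixed) {
      pooled[i, grep("^u\\[", colnames(pooled), value = TRUE)]
    }
    theta <- exp(linear_predictor(pooled[i, cn], object$data, u = u))
    stats::rbinom(object$data$n, 1, pmin(theta, 1))
  }, integer(object$data$n))
  matrix(out, ncol = nsim)
}
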