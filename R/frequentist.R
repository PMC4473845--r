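#' Poisson regression with robust (sandwich) variance
#'
#' The standard frequentist comparator for relative-risk estimation on a
#' binary outcome: a Poisson GLM with log link fitted by IRLS, with the
#' HC0 sandwich estimator for the coefficient covariance. Consistent for
#' the RR/PR but not constrained, so fitted probabilities can exceed 1.
#'
#' @param data An [rr_data()] object with a binary (or count) outcome.
#' @return An object of class `"rr_freq"` (see [rr_freq()]).
#' @export
fit_poisson_robust <- function(data) {
  stopifnot(inherits(data, "rr_data"))
  fit <- suppressWarnings(stats::glm(
    data$y ~ data$x - 1,
    family = stats::poisson(),
    control = stats::glm.control(epsilon = 1e-12, maxit = 100)
  ))
  beta <- unname(fit$coefficients)
  names(beta) <- colnames(data$x)
  converged <- fit$converged && all(is.finite(beta)) && max(abs(beta)) < 30
  vc_model <- stats::summary.glm(fit)$cov.unscaled
  vc_robust <- sandwich::vcovHC(fit, type = "HC0")
  dimnames(vc_model) <- dimnames(vc_robust) <- list(names(beta), names(beta))
  new_rr_freq(
    beta = beta, vcov_model = vc_model, vcov_robust = vc_robust,
    converged = converged, n_iter = fit$iter, family = "poisson",
    method = "poisson-robust", data = data
  )
}

#' Constrained maximum likelihood for the log-binomial model
#'
#' Maximizes the log-binomial likelihood by Fisher scoring with
#' step-halving whenever a step would leave the valid region
#' `max(eta) <= 0` (every fitted probability <= 1) or decrease the
#' likelihood. When the optimum is pinned to the constraint boundary, or
#' the iteration cap is reached, the fit is flagged `converged = FALSE`
#' but coefficients are still reported -- non-convergence here is a
#' reported state, not an error, because this is exactly the failure mode
#' that motivates the Bayesian treatment.
#'
#' @param data An [rr_data()] object with a binary outcome.
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the score norm.
#' @return An object of class `"rr_freq"`.
#' @export
fit_logbinomial_mle <- function(data, max_iter = 200, tol = 1e-8) {
  stopifnot(inherits(data, "rr_data"), data$family == "binomial")
  X <- data$x
  y <- data$y
  beta <- initialize_state(data)$beta
  eta <- drop(X %*% beta)
  ll <- loglik_from_eta(eta, y)
  boundary <- FALSE
  it <- 0L
  grad_norm <- Inf
  for (it in seq_len(max_iter)) {
    theta <- exp(eta)
    r <- (y - theta) / (1 - theta) # d loglik / d eta
    score <- drop(crossprod(X, r))
    w <- theta / (1 - theta) # expected information weight, log link
    XtWX <- crossprod(X, X * w)
    step <- tryCatch(solve(XtWX, score), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      eta_new <- drop(X %*% beta_new)
      # keep strictly inside: theta = 1 makes the weights blow up
      if (max(eta_new) <= -1e-10) {
        ll_new <- loglik_from_eta(eta_new, y)
        if (ll_new >= ll - 1e-12) break
      }
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    if (lambda < 1e-10) {
      boundary <- TRUE
      break
    }
    beta <- beta_new
    eta <- eta_new
    ll <- ll_new
    grad_norm <- sqrt(sum(score^2))
    if (grad_norm < tol && lambda == 1) break
  }
  theta <- exp(eta)
  at_boundary <- max(eta) > -1e-7
  converged <- !boundary && !at_boundary && grad_norm < max(tol, 1e-6) && it < max_iter
  w <- theta / (1 - theta)
  XtWX <- crossprod(X, X * w)
  vc_model <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  s <- X * ((y - theta) / (1 - theta))
  meat <- crossprod(s)
  vc_robust <- tryCatch(vc_model %*% meat %*% vc_model,
    error = function(e) matrix(NA_real_, ncol(X), ncol(X))
  )
  names(beta) <- colnames(X)
  dimnames(vc_model) <- dimnames(vc_robust) <- list(names(beta), names(beta))
  if (!converged) {
    warning("log-binomial MLE did not converge (boundary or iteration cap); results reported anyway")
  }
  new_rr_freq(
    beta = beta, vcov_model = vc_model, vcov_robust = vc_robust,
    converged = converged, n_iter = it, family = "logbinomial",
    method = "logbin-mle", data = data, loglik = ll
  )
}

#' Generalized estimating equations with exchangeable correlation
#'
#' Marginal log-link model for clustered binary data, fitted by the
#' standard GEE iteration: a moment estimator of the exchangeable
#' within-cluster correlation alpha from Pearson residuals, working-
#' covariance weighted estimating equations for the coefficients, and a
#' cluster-robust sandwich covariance. The exchangeable structure is what
#' makes alpha interpretable as an ICC estimate. With the
#' `"logbinomial"` family (binomial variance mu(1-mu), scale fixed at 1)
#' coefficient updates are step-halved into the valid region exactly as
#' in [fit_logbinomial_mle()]; with `"poisson"` (variance mu, scale
#' moment-estimated) no constraint applies.
#'
#' @param data An [rr_data()] object with cluster labels (>= 2 clusters).
#' @param family `"poisson"` or `"logbinomial"` (log link both).
#' @param max_iter,tol Iteration control.
#' @return An object of class `"rr_freq"` with the `alpha` estimate.
#' @export
fit_gee <- function(data, family = c("poisson", "logbinomial"), max_iter = 100, tol = 1e-8) {
  stopifnot(inherits(data, "rr_data"))
  family <- match.arg(family)
  if (is.null(data$cluster)) stop("GEE needs cluster labels")
  m <- length(data$cluster_labels)
  if (m < 2) stop("GEE needs at least 2 clusters")
  X <- data$x
  y <- data$y
  p1 <- ncol(X)
  rows <- split(seq_len(data$n), data$cluster)
  npairs <- sum(vapply(rows, function(r) length(r) * (length(r) - 1) / 2, numeric(1)))

  vfun <- if (family == "poisson") {
    function(mu) mu
  } else {
    function(mu) mu * (1 - mu)
  }
  beta <- if (family == "poisson") {
    poisson_coef(X, y)
  } else {
    initialize_state(data)$beta
  }
  eta <- drop(X %*% beta)
  alpha <- 0
  phi <- 1
  converged <- FALSE
  alpha_warned <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    mu <- exp(eta)
    v <- vfun(mu)
    e <- (y - mu) / sqrt(pmax(v, 1e-12))
    if (family == "poisson") phi <- sum(e^2) / max(data$n - p1, 1)
    if (npairs > p1) {
      s <- 0
      for (r in rows) {
        if (length(r) > 1) s <- s + (sum(e[r])^2 - sum(e[r]^2)) / 2
      }
      alpha_new <- s / ((npairs - p1) * phi)
      if (alpha_new < 0) {
        if (!alpha_warned) {
          warning("negative moment estimate of the exchangeable correlation; floored at 0")
          alpha_warned <- TRUE
        }
        alpha_new <- 0
      }
      alpha <- min(alpha_new, 0.99)
    }
    # working-covariance weighted scoring step; exchangeable inverse in
    # closed form: R^-1 = [I - alpha/(1+(n_i-1)alpha) J] / (1-alpha)
    A <- matrix(0, p1, p1)
    g <- numeric(p1)
    for (r in rows) {
      ni <- length(r)
      Di <- X[r, , drop = FALSE] * mu[r] # d mu / d beta
      si <- sqrt(pmax(v[r], 1e-12))
      DS <- Di / si # A^{-1/2} D
      rs <- (y[r] - mu[r]) / si
      c1 <- 1 / (1 - alpha)
      c2 <- alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
      Rin_DS <- c1 * DS - c2 * matrix(colSums(DS), ni, p1, byrow = TRUE)
      A <- A + crossprod(DS, Rin_DS)
      g <- g + drop(crossprod(Rin_DS, rs))
    }
    step <- tryCatch(solve(A, g), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      eta_new <- drop(X %*% beta_new)
      if (family == "poisson" || max(eta_new) <= -1e-10) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    if (lambda < 1e-10) break
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    eta <- eta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  mu <- exp(eta)
  v <- vfun(mu)
  A <- matrix(0, p1, p1)
  Bm <- matrix(0, p1, p1)
  for (r in rows) {
    ni <- length(r)
    Di <- X[r, , drop = FALSE] * mu[r]
    si <- sqrt(pmax(v[r], 1e-12))
    DS <- Di / si
    rs <- (y[r] - mu[r]) / si
    c1 <- 1 / (1 - alpha)
    c2 <- alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
    Rin_DS <- c1 * DS - c2 * matrix(colSums(DS), ni, p1, byrow = TRUE)
    A <- A + crossprod(DS, Rin_DS)
    gi <- drop(crossprod(Rin_DS, rs))
    Bm <- Bm + tcrossprod(gi)
  }
  Ainv <- tryCatch(solve(A), error = function(e) matrix(NA_real_, p1, p1))
  vc_model <- Ainv * phi
  vc_robust <- Ainv %*% Bm %*% Ainv
  names(beta) <- colnames(X)
  dimnames(vc_model) <- dimnames(vc_robust) <- list(names(beta), names(beta))
  if (!converged) {
    warning("GEE iteration did not converge; results reported anyway")
  }
  new_rr_freq(
    beta = beta, vcov_model = vc_model, vcov_robust = vc_robust,
    converged = converged, n_iter = it,
    family = family, method = paste0("gee-", if (family == "poisson") "poisson" else "logbin"),
    data = data, alpha = max(0, min(alpha, 1 - 1e-12))
  )
}

new_rr_freq <- function(beta, vcov_model, vcov_robust, converged, n_iter,
                        family, method, data, alpha = NULL, loglik = NULL) {
  structure(
    list(
      beta = beta, vcov_model = vcov_model, vcov_robust = vcov_robust,
      converged = converged, n_iter = n_iter, family = family,
      method = method, alpha = alpha, loglik = loglik,
      n = data$n, coef_names = names(beta)
    ),
    class = "rr_freq"
  )
}

#' Fit a frequentist relative-risk comparator model
#'
#' Dispatcher over the three comparator fits: [fit_poisson_robust()],
#' [fit_logbinomial_mle()] and [fit_gee()].
#'
#' @param data An [rr_data()] object.
#' @param method One of `"poisson-robust"`, `"logbin-mle"`,
#'   `"gee-poisson"`, `"gee-logbin"`.
#' @return An object of class `"rr_freq"`.
#' @export
rr_freq <- function(data, method = c("poisson-robust", "logbin-mle", "gee-poisson", "gee-logbin")) {
  method <- match.arg(method)
  switch(method,
    "poisson-robust" = fit_poisson_robust(data),
    "logbin-mle" = fit_logbinomial_mle(data),
    "gee-poisson" = fit_gee(data, family = "poisson"),
    "gee-logbin" = fit_gee(data, family = "logbinomial")
  )
}

#' @export
coef.rr_freq <- function(object, ...) object$beta

#' @export
vcov.rr_freq <- function(object, robust = TRUE, ...) {
  if (robust) object$vcov_robust else object$vcov_model
}

#' @export
confint.rr_freq <- function(object, parm, level = 0.95, robust = TRUE, ...) {
  se <- sqrt(diag(vcov.rr_freq(object, robust = robust)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$beta - z * se, object$beta + z * se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2)), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.rr_freq <- function(x, ...) {
  cat("<rr_freq> ", x$method, " fit, n = ", x$n,
    if (!x$converged) "  [did NOT converge]", "\n",
    sep = ""
  )
  print(summary(x), ...)
  invisible(x)
}

#' Summary table of a frequentist fit
#'
#' Same schema as [summarize_chains()] so fits can be fed to
#' [compare_methods()]: Wald 95% intervals from the robust covariance on
#' the coefficient scale, plus exponentiated (RR/PR) rows for the
#' non-intercept coefficients, plus the exchangeable-correlation ICC
#' estimate for GEE fits.
#'
#' @param object An `rr_freq` fit.
#' @param level Confidence level.
#' @param robust Use the sandwich covariance (default) or the model-based one.
#' @param ... Unused.
#' @return A data.frame with columns `parameter`, `scale`, `estimate`,
#'   `lower`, `upper`, `level`.
#' @export
summary.rr_freq <- function(object, level = 0.95, robust = TRUE, ...) {
  ci <- confint.rr_freq(object, level = level, robust = robust)
  out <- data.frame(
    parameter = object$coef_names, scale = "coefficient",
    estimate = unname(object$beta), lower = ci[, 1], upper = ci[, 2],
    level = level, stringsAsFactors = FALSE
  )
  ratio_for <- grep("Intercept", object$coef_names, invert = TRUE, value = TRUE)
  if (length(ratio_for)) {
    i <- match(ratio_for, object$coef_names)
    out <- rbind(out, data.frame(
      parameter = paste0(ratio_for, " RR"), scale = "ratio",
      estimate = exp(unname(object$beta[i])), lower = exp(ci[i, 1]), upper = exp(ci[i, 2]),
      level = level, stringsAsFactors = FALSE
    ))
  }
  if (!is.null(object$alpha)) {
    out <- rbind(out, data.frame(
      parameter = "ICC", scale = "derived", estimate = object$alpha,
      lower = NA_real_, upper = NA_real_, level = level, stringsAsFactors = FALSE
    ))
  }
  rownames(out) <- NULL
  out
}

#' Fitted probabilities of a frequentist fit
#'
#' @param object An `rr_freq` fit.
#' @param data The dataset to predict for (an [rr_data()]).
#' @param ... Unused.
#' @return Vector of `exp(x_i' beta)`; for the unconstrained Poisson
#'   model these can exceed 1.
#' @export
predict.rr_freq <- function(object, data, ...) {
  exp(linear_predictor(object$beta, data))
}
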