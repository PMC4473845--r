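#' Assemble a relative-risk regression dataset
#'
#' Bundles an outcome vector, a design matrix and an optional cluster
#' indicator into the container used by every fitting routine in the
#' package. The design matrix must carry an explicit intercept: its first
#' column is all ones. Categorical covariates are expanded to indicator
#' columns by the caller (reference level omitted), matching how results
#' are tabulated.
#'
#' @param y Outcome vector. For a binomial outcome, values in \{0, 1\}.
#'   For a polytomous outcome, integer category codes in \{0, ..., J-1\}
#'   with 0 the reference category and J >= 2.
#' @param x Numeric design matrix, n rows, first column all ones.
#' @param cluster Optional vector of cluster labels (factor, character or
#'   integer), length n. Present for clustered designs only.
#' @param family `"auto"` (default) infers `"binomial"` when `max(y) <= 1`
#'   and `"multinomial"` otherwise; or force one of the two.
#' @return An object of class `"rr_data"`: a list with elements `y`
#'   (integer outcome), `x` (design matrix), `cluster` (integer index
#'   1..m or `NULL`), `cluster_labels`, `n`, `p` (number of covariates,
#'   excluding the intercept), `J` (number of outcome categories) and
#'   `family`.
#' @examples
#' d <- rr_data(c(1, 0, 1), cbind(1, c(0.2, -1, 0.5)))
#' d$n
#' @export
rr_data <- function(y, x, cluster = NULL, family = c("auto", "binomial", "multinomial")) {
  family <- match.arg(family)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(y) || anyNA(x)) stop("missing values are not supported")
  if (nrow(x) != length(y)) {
    stop("design matrix has ", nrow(x), " rows but outcome has length ", length(y))
  }
  if (!all(x[, 1] == 1)) stop("first design column must be an all-ones intercept")
  if (any(y != round(y)) || any(y < 0)) stop("outcome must contain non-negative integer codes")
  y <- as.integer(y)
  if (family == "auto") family <- if (max(y) <= 1L) "binomial" else "multinomial"
  J <- if (family == "binomial") 2L else max(2L, max(y) + 1L)
  if (family == "binomial" && any(y > 1L)) stop("binomial outcome must be 0/1")
  if (family == "multinomial" && J < 2L) stop("polytomous outcome needs J >= 2 categories")
  if (is.null(colnames(x))) {
    colnames(x) <- c("(Intercept)", if (ncol(x) > 1L) paste0("x", seq_len(ncol(x) - 1L)))
  }
  cluster_labels <- NULL
  cl_index <- NULL
  if (!is.null(cluster)) {
    if (anyNA(cluster)) stop("missing cluster labels are not supported")
    if (length(cluster) != length(y)) stop("cluster vector length must match the outcome")
    f <- factor(cluster)
    cluster_labels <- levels(f)
    cl_index <- as.integer(f)
  }
  structure(
    list(
      y = y, x = x, cluster = cl_index, cluster_labels = cluster_labels,
      n = length(y), p = ncol(x) - 1L, J = J, family = family
    ),
    class = "rr_data"
  )
}

#' @export
print.rr_data <- function(x, ...) {
  cat("<rr_data> ", x$n, " observations, ", x$p, " covariate(s), family ",
    x$family, if (x$family == "multinomial") paste0(" (J = ", x$J, ")"), "\n",
    sep = ""
  )
  if (!is.null(x$cluster)) {
    cat("  clustered: ", length(x$cluster_labels), " clusters, sizes ",
      min(tabulate(x$cluster)), "-", max(tabulate(x$cluster)), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Read / write datasets as delimited text
#'
#' The on-disk dialect is a header CSV with columns `outcome`, then the
#' covariates (intercept column omitted), then an optional `cluster`
#' column. `read_rr_data()` prepends the intercept column.
#'
#' @param path File path.
#' @param family Passed to [rr_data()].
#' @return `read_rr_data()` returns an `rr_data`; `write_rr_data()`
#'   returns `path` invisibly.
#' @export
read_rr_data <- function(path, family = "auto") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"outcome" %in% names(df)) stop("file must have an 'outcome' column")
  cl <- if ("cluster" %in% names(df)) df$cluster
  covs <- df[, setdiff(names(df), c("outcome", "cluster")), drop = FALSE]
  x <- cbind(`(Intercept)` = 1, as.matrix(covs))
  rr_data(df$outcome, x, cluster = cl, family = family)
}

#' @rdname read_rr_data
#' @param data An `rr_data` object.
#' @export
write_rr_data <- function(data, path) {
  stopifnot(inherits(data, "rr_data"))
  df <- data.frame(outcome = data$y, check.names = FALSE)
  if (data$p > 0L) {
    df <- cbind(df, as.data.frame(data$x[, -1L, drop = FALSE]))
  }
  if (!is.null(data$cluster)) df$cluster <- data$cluster_labels[data$cluster]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Prior settings for the Bayesian models
#'
#' Coefficients get independent normal priors (vague by default: mean 0,
#' variance 1e6). The random-effect standard deviation gets a uniform
#' prior on `[sd_lower, sd_upper]` (default 0.01 to 100).
#'
#' @param coef_mean,coef_var Normal prior mean and variance for every
#'   regression coefficient (also applied to each row of the multinomial
#'   coefficient matrix).
#' @param sd_lower,sd_upper Support of the uniform prior for the
#'   cluster-effect standard deviation.
#' @return An object of class `"rr_prior"`.
#' @export
prior_spec <- function(coef_mean = 0, coef_var = 1e6, sd_lower = 0.01, sd_upper = 100) {
  if (coef_var <= 0) stop("coef_var must be positive")
  if (!(sd_lower > 0 && sd_lower < sd_upper)) stop("need 0 < sd_lower < sd_upper")
  structure(
    list(
      coef_mean = coef_mean, coef_var = coef_var,
      sd_lower = sd_lower, sd_upper = sd_upper
    ),
    class = "rr_prior"
  )
}

# Coerce the flexible state argument (vector / matrix / list) used across
# the log-density functions into list(beta=, u=, sigma_u=, B=).
as_rr_state <- function(state) {
  if (is.list(state) && !is.data.frame(state)) {
    out <- list(
      beta = state$beta, u = state$u, sigma_u = state$sigma_u,
      B = state$B
    )
  } else if (is.matrix(state)) {
    out <- list(beta = NULL, u = NULL, sigma_u = NULL, B = state)
  } else {
    out <- list(beta = as.numeric(state), u = NULL, sigma_u = NULL, B = NULL)
  }
  out
}

#' Linear predictor of a log-link model
#'
#' Computes `eta = X beta`, plus the cluster effect `u` at each row's
#' cluster when supplied. The per-row probability of the log-binomial
#' model is `exp(eta)`.
#'
#' @param beta Coefficient vector, length `ncol(x)`.
#' @param data An [rr_data()] object.
#' @param u Optional cluster-effect vector, one entry per distinct cluster.
#' @return Numeric vector of length `data$n`.
#' @export
linear_predictor <- function(beta, data, u = NULL) {
  stopifnot(inherits(data, "rr_data"))
  beta <- as.numeric(beta)
  if (length(beta) != ncol(data$x)) {
    stop(
      "coefficient vector has length ", length(beta),
      " but the design matrix has ", ncol(data$x), " columns"
    )
  }
  eta <- drop(data$x %*% beta)
  if (!is.null(u)) {
    if (is.null(data$cluster)) stop("cluster effects supplied but the data have no clusters")
    if (length(u) != length(data$cluster_labels)) {
      stop(
        "cluster-effect vector has length ", length(u), " but there are ",
        length(data$cluster_labels), " clusters"
      )
    }
    eta <- eta + u[data$cluster]
  }
  eta
}

#' Fitted probabilities of the log-link models
#'
#' For a binomial model (`coef` a vector), returns `exp(eta)` per row.
#' For a multinomial model (`coef` a (J-1) x (p+1) matrix, one row per
#' non-reference category), returns an n x J matrix whose first column is
#' the reference-category probability, filled in as the complement
#' `1 - sum_j theta_ij`. No clipping is performed: out-of-range values
#' are representable and detected by [constraint_ok()].
#'
#' @param coef Coefficient vector (binomial) or matrix (multinomial).
#' @inheritParams linear_predictor
#' @return Numeric vector (binomial) or n x J matrix with column names
#'   `cat0..cat(J-1)` (multinomial).
#' @export
rr_probabilities <- function(coef, data, u = NULL) {
  st <- as_rr_state(coef)
  if (!is.null(st$B)) {
    B <- st$B
    if (ncol(B) != ncol(data$x)) stop("coefficient matrix does not conform to the design")
    Theta <- exp(data$x %*% t(B))
    ref <- 1 - rowSums(Theta)
    out <- cbind(ref, Theta)
    colnames(out) <- paste0("cat", seq_len(ncol(out)) - 1L)
    out
  } else {
    exp(linear_predictor(st$beta, data, u))
  }
}

#' Check the valid-probability restriction
#'
#' The log link does not keep probabilities below one, so the coefficient
#' space must be restricted: every fitted probability must satisfy
#' `theta_i <= 1` (binomial), and for a multinomial model additionally
#' the reference-category complement must be non-negative. The inequality
#' is non-strict: the boundary `theta_i = 1` is allowed (the likelihood
#' handles `log 0` separately). For mixed models the restriction is
#' evaluated at the supplied cluster effects `u`, i.e. for the observed
#' clusters at their current values.
#'
#' @inheritParams rr_probabilities
#' @return `TRUE` or `FALSE`.
#' @export
constraint_ok <- function(coef, data, u = NULL) {
  st <- as_rr_state(coef)
  if (!is.null(st$B)) {
    th <- rr_probabilities(st$B, data)
    all(th[, -1L, drop = FALSE] <= 1) && all(th[, 1L] >= 0)
  } else {
    all(linear_predictor(st$beta, data, u) <= 0)
  }
}

#' Log-likelihood of the log-binomial model
#'
#' `sum_i [y_i log theta_i + (1 - y_i) log(1 - theta_i)]` with
#' `theta_i = exp(eta_i)`. Returns `-Inf` whenever the valid-probability
#' restriction fails, or when some `theta_i = 1` coincides with
#' `y_i = 0` (a log-zero term).
#'
#' @inheritParams linear_predictor
#' @return A scalar, always `<= 0`.
#' @export
logbin_loglik <- function(beta, data, u = NULL) {
  if (data$family != "binomial") {
    stop("logbin_loglik() needs a binomial outcome; see logmultinomial_loglik()")
  }
  eta <- linear_predictor(beta, data, u)
  if (any(eta > 0)) return(-Inf)
  loglik_from_eta(eta, data$y)
}

# Binary log-likelihood given a valid linear predictor (all eta <= 0).
# Split by outcome so that 0 * log(0) never produces NaN.
loglik_from_eta <- function(eta, y) {
  ll0 <- sum(log1p(-exp(eta[y == 0L])))
  if (!is.finite(ll0)) return(-Inf)
  sum(eta[y == 1L]) + ll0
}

#' Log-likelihood of the log-multinomial model
#'
#' Each non-reference category j has probability
#' `theta_ij = exp(x_i' B_j)`; the reference probability is the
#' complement `1 - sum_j theta_ij`. Returns `-Inf` on any constraint
#' violation, or when an observed category has probability zero.
#'
#' @param B (J-1) x (p+1) coefficient matrix, row j for category j.
#' @param data An [rr_data()] object with a polytomous outcome.
#' @return A scalar, always `<= 0`.
#' @export
logmultinomial_loglik <- function(B, data) {
  B <- as.matrix(B)
  if (any(data$y < 0L) || any(data$y > nrow(B))) {
    stop("outcome categories must lie in 0..", nrow(B))
  }
  Eta <- data$x %*% t(B)
  Theta <- exp(Eta)
  ref <- 1 - rowSums(Theta)
  if (any(Theta > 1) || any(ref < 0)) return(-Inf)
  loglik_from_theta_mn(Eta, ref, data$y)
}

loglik_from_theta_mn <- function(Eta, ref, y) {
  is_ref <- y == 0L
  ll_ref <- sum(log(ref[is_ref]))
  if (!is.finite(ll_ref)) return(-Inf)
  nonref <- which(!is_ref)
  ll_ref + sum(Eta[cbind(nonref, y[nonref])])
}

#' Log prior density
#'
#' Independent normal log-densities over all regression coefficients
#' (every entry of `beta`, or of the multinomial matrix `B`), plus the
#' uniform log-density for the random-effect standard deviation when the
#' state carries one (`-Inf` outside its support). Cluster effects `u`
#' are not prior terms; their normal density enters [log_posterior()].
#'
#' @param state Coefficient vector, coefficient matrix, or a list with
#'   elements `beta` (and optionally `u`, `sigma_u`) or `B`.
#' @param prior A [prior_spec()].
#' @return A scalar log-density.
#' @export
log_prior <- function(state, prior = prior_spec()) {
  st <- as_rr_state(state)
  coefs <- if (!is.null(st$B)) as.numeric(st$B) else st$beta
  lp <- sum(stats::dnorm(coefs, prior$coef_mean, sqrt(prior$coef_var), log = TRUE))
  if (!is.null(st$sigma_u)) {
    lp <- lp + stats::dunif(st$sigma_u, prior$sd_lower, prior$sd_upper, log = TRUE)
  }
  lp
}

#' Log posterior density (unnormalized)
#'
#' Likelihood plus prior; for mixed models the cluster effects contribute
#' `sum_i log N(u_i; 0, sigma_u^2)`. `-Inf` from any component (including
#' the valid-probability restriction) propagates.
#'
#' @inheritParams log_prior
#' @param data An [rr_data()] object matching the state's family.
#' @return A scalar log-density.
#' @export
log_posterior <- function(state, data, prior = prior_spec()) {
  st <- as_rr_state(state)
  lp <- log_prior(st, prior)
  if (!is.finite(lp)) return(-Inf)
  if (!is.null(st$B)) {
    ll <- logmultinomial_loglik(st$B, data)
  } else {
    ll <- logbin_loglik(st$beta, data, u = st$u)
    if (!is.null(st$u)) {
      if (is.null(st$sigma_u)) stop("a mixed state needs sigma_u")
      lp <- lp + sum(stats::dnorm(st$u, 0, st$sigma_u, log = TRUE))
    }
  }
  ll + lp
}
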