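#' MCMC run settings
#'
#' Defaults mirror the smallest run reported for the models this package
#' targets: 3 chains, burn-in of 50,000 sweeps, 50,000 further sweeps
#' thinned by 100. At least 1000 retained draws in total (across chains)
#' are required for estimation.
#'
#' @param n_chains Number of independent chains (>= 2).
#' @param n_iter Total sweeps per chain, including burn-in.
#' @param burn_in Sweeps discarded from the front of each chain; proposal
#'   scales adapt only during this phase.
#' @param thin Keep every `thin`-th sweep after burn-in.
#' @param seed Integer seed; chain sub-seeds are derived from it.
#' @param target_accept Target acceptance rate of the component-wise
#'   random-walk proposals during adaptation.
#' @return An object of class `"rr_chain_settings"`.
#' @export
chain_settings <- function(n_chains = 3, n_iter = 100000, burn_in = 50000,
                           thin = 100, seed = 1, target_accept = 0.30) {
  if (n_chains < 2) stop("need at least 2 chains")
  if (thin < 1) stop("thin must be >= 1")
  if (burn_in < 0 || burn_in >= n_iter) stop("need 0 <= burn_in < n_iter")
  if (!(target_accept > 0 && target_accept < 1)) stop("target_accept must lie in (0,1)")
  retained <- n_chains * floor((n_iter - burn_in) / thin)
  if (retained < 1000) {
    stop(
      "settings retain only ", retained,
      " draws in total; at least 1000 are required for estimation"
    )
  }
  structure(
    list(
      n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
      burn_in = as.integer(burn_in), thin = as.integer(thin),
      seed = as.integer(seed), target_accept = target_accept
    ),
    class = "rr_chain_settings"
  )
}

# ---- internal sampling context ------------------------------------------

# Precomputations shared by every sweep. For binary models the linear
# predictor is cached and updated incrementally (a coefficient move shifts
# eta by X[,j]*delta; a cluster-effect move touches one cluster's rows).
make_ctx <- function(data, prior) {
  mixed <- !is.null(data$cluster) && data$family == "binomial"
  ctx <- list(
    X = data$x, y = data$y, n = data$n, J = data$J,
    family = data$family, mixed = mixed, prior = prior,
    idx1 = which(data$y == 1L), idx0 = which(data$y == 0L),
    sd0 = sqrt(prior$coef_var), m0 = prior$coef_mean
  )
  if (mixed) {
    rows <- split(seq_len(data$n), data$cluster)
    ctx$rows1 <- lapply(rows, function(r) r[data$y[r] == 1L])
    ctx$rows0 <- lapply(rows, function(r) r[data$y[r] == 0L])
    ctx$rows <- rows
    ctx$m <- length(rows)
  }
  if (data$family == "multinomial") {
    ctx$idx_ref <- which(data$y == 0L)
    ctx$rows_cat <- lapply(seq_len(data$J - 1L), function(j) which(data$y == j))
  }
  ctx
}

# Initialize the cached pieces (eta / Eta, log-likelihood) for a state.
cache_state <- function(st, ctx) {
  if (ctx$family == "multinomial") {
    st$Eta <- ctx$X %*% t(st$B)
    st$Theta <- exp(st$Eta)
    st$ref <- 1 - rowSums(st$Theta)
    st$ll <- if (any(st$Theta > 1) || any(st$ref < 0)) {
      -Inf
    } else {
      loglik_from_theta_mn(st$Eta, st$ref, ctx$y)
    }
  } else {
    st$beta <- unname(st$beta)
    st$eta <- drop(ctx$X %*% st$beta)
    if (ctx$mixed) st$eta <- st$eta + st$u[unlist0(ctx)]
    st$ll <- if (any(st$eta > 0)) -Inf else loglik_from_eta(st$eta, ctx$y)
  }
  st
}

unlist0 <- function(ctx) {
  idx <- integer(ctx$n)
  for (i in seq_along(ctx$rows)) idx[ctx$rows[[i]]] <- i
  idx
}

cluster_ll <- function(eta, r1, r0) {
  sum(eta[r1]) + sum(log1p(-exp(eta[r0])))
}

# One component-wise random-walk Metropolis sweep over a binary (possibly
# mixed) state. Returns the state plus realized acceptance probabilities.
sweep_binary <- function(st, ctx, scales) {
  K <- length(scales)
  alpha <- numeric(K)
  p1 <- ncol(ctx$X)
  for (j in seq_len(p1)) {
    prop <- st$beta[j] + scales[j] * stats::rnorm(1)
    eta_new <- st$eta + ctx$X[, j] * (prop - st$beta[j])
    if (any(eta_new > 0)) next
    ll_new <- loglik_from_eta(eta_new, ctx$y)
    logr <- ll_new - st$ll +
      stats::dnorm(prop, ctx$m0, ctx$sd0, log = TRUE) -
      stats::dnorm(st$beta[j], ctx$m0, ctx$sd0, log = TRUE)
    alpha[j] <- min(1, exp(logr))
    if (log(stats::runif(1)) < logr) {
      st$beta[j] <- prop
      st$eta <- eta_new
      st$ll <- ll_new
    }
  }
  if (ctx$mixed) {
    for (i in seq_len(ctx$m)) {
      k <- p1 + i
      d <- scales[k] * stats::rnorm(1)
      r1 <- ctx$rows1[[i]]
      r0 <- ctx$rows0[[i]]
      e1 <- st$eta[r1] + d
      e0 <- st$eta[r0] + d
      if (any(e1 > 0) || any(e0 > 0)) next
      c_old <- cluster_ll(st$eta, r1, r0)
      c_new <- sum(e1) + sum(log1p(-exp(e0)))
      u_new <- st$u[i] + d
      logr <- c_new - c_old +
        stats::dnorm(u_new, 0, st$sigma_u, log = TRUE) -
        stats::dnorm(st$u[i], 0, st$sigma_u, log = TRUE)
      alpha[k] <- min(1, exp(logr))
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        st$u[i] <- u_new
        st$eta[r1] <- e1
        st$eta[r0] <- e0
        st$ll <- st$ll + (c_new - c_old)
      }
    }
    # sigma_u: random walk on the log scale with a Jacobian correction;
    # the uniform prior enters only through its support.
    k <- p1 + ctx$m + 1L
    ls_new <- log(st$sigma_u) + scales[k] * stats::rnorm(1)
    s_new <- exp(ls_new)
    if (s_new >= ctx$prior$sd_lower && s_new <= ctx$prior$sd_upper) {
      logr <- sum(stats::dnorm(st$u, 0, s_new, log = TRUE)) -
        sum(stats::dnorm(st$u, 0, st$sigma_u, log = TRUE)) +
        (ls_new - log(st$sigma_u))
      alpha[k] <- min(1, exp(logr))
      if (log(stats::runif(1)) < logr) st$sigma_u <- s_new
    }
  }
  list(state = st, alpha = alpha)
}

sweep_multinomial <- function(st, ctx, scales) {
  p1 <- ncol(ctx$X)
  Jm1 <- ctx$J - 1L
  alpha <- numeric(Jm1 * p1)
  for (j in seq_len(Jm1)) {
    for (k in seq_len(p1)) {
      idx <- (j - 1L) * p1 + k
      prop <- st$B[j, k] + scales[idx] * stats::rnorm(1)
      col_new <- st$Eta[, j] + ctx$X[, k] * (prop - st$B[j, k])
      th_new <- exp(col_new)
      ref_new <- st$ref + st$Theta[, j] - th_new
      if (any(th_new > 1) || any(ref_new < 0)) next
      rj <- ctx$rows_cat[[j]]
      c_old <- sum(log(st$ref[ctx$idx_ref])) + sum(st$Eta[rj, j])
      c_new <- sum(log(ref_new[ctx$idx_ref])) + sum(col_new[rj])
      logr <- c_new - c_old +
        stats::dnorm(prop, ctx$m0, ctx$sd0, log = TRUE) -
        stats::dnorm(st$B[j, k], ctx$m0, ctx$sd0, log = TRUE)
      alpha[idx] <- min(1, exp(logr))
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        st$B[j, k] <- prop
        st$Eta[, j] <- col_new
        st$Theta[, j] <- th_new
        st$ref <- ref_new
        st$ll <- st$ll + (c_new - c_old)
      }
    }
  }
  list(state = st, alpha = alpha)
}

#' One Metropolis sweep over every model parameter
#'
#' Performs a single component-wise random-walk Metropolis update of every
#' coefficient (and, for mixed models, every cluster effect and the
#' random-effect standard deviation, the latter on the log scale with a
#' Jacobian correction). Proposals that violate the valid-probability
#' restriction or leave the prior support have posterior density zero and
#' are rejected, which preserves detailed balance with respect to
#' [log_posterior()].
#'
#' @param state A state list (`beta`, optionally `u` and `sigma_u`) or a
#'   multinomial coefficient matrix `B` (or a list with element `B`).
#' @param data,prior As in [log_posterior()]. The state must satisfy
#'   [constraint_ok()].
#' @param scales Vector of proposal standard deviations, one per scalar
#'   parameter, in update order (coefficients, then cluster effects, then
#'   `sigma_u`; for a multinomial model, `B` in row-major order).
#' @return The new state in the same shape as the input.
#' @export
metropolis_sweep <- function(state, data, prior = prior_spec(), scales) {
  ctx <- make_ctx(data, prior)
  st <- as_rr_state(state)
  mn <- !is.null(st$B)
  if (!mn && ctx$mixed && is.null(st$u)) {
    stop("mixed-model data need a state with cluster effects u and sigma_u")
  }
  st <- cache_state(st, ctx)
  if (!is.finite(st$ll)) {
    stop("initial state violates the valid-probability restriction (theta_i <= 1)")
  }
  res <- if (mn) sweep_multinomial(st, ctx, scales) else sweep_binary(st, ctx, scales)
  out <- res$state
  if (mn) {
    if (is.matrix(state)) out$B else list(B = out$B)
  } else if (ctx$mixed) {
    list(beta = out$beta, u = out$u, sigma_u = out$sigma_u)
  } else if (is.list(state)) list(beta = out$beta) else out$beta
}

#' Initial state for the sampler
#'
#' Coefficients start at the robust-Poisson fit; if that start violates
#' the valid-probability restriction the intercept is shifted down by
#' `max(eta) + delta` so that the largest fitted probability is
#' `exp(-delta) < 1`. Cluster effects start at zero and `sigma_u` at 0.5.
#' For a multinomial model each category row starts at the Poisson fit of
#' its indicator outcome, with all intercepts shifted down together until
#' every reference-category complement is positive. A small normal jitter
#' (`jitter_sd`) can be requested to overdisperse chain starts; the shift
#' is re-applied afterwards so the returned state is always valid.
#'
#' @inheritParams log_posterior
#' @param jitter_sd Standard deviation of the coefficient jitter (0 = none).
#' @param delta Gap kept below the constraint boundary on the log scale.
#' @return A valid state list (`beta`/`u`/`sigma_u` or `B`).
#' @export
initialize_state <- function(data, prior = prior_spec(), jitter_sd = 0, delta = 0.01) {
  if (data$family == "multinomial") {
    p1 <- ncol(data$x)
    B <- matrix(0, data$J - 1L, p1)
    for (j in seq_len(data$J - 1L)) {
      B[j, ] <- poisson_coef(data$x, as.integer(data$y == j))
    }
    if (jitter_sd > 0) B <- B + matrix(stats::rnorm(length(B), 0, jitter_sd), nrow(B))
    s <- max(rowSums(exp(data$x %*% t(B))))
    if (s >= 1) B[, 1L] <- B[, 1L] - (log(s) + delta)
    if (!constraint_ok(B, data)) {
      stop("could not find a starting state satisfying the probability constraints")
    }
    return(list(B = B))
  }
  beta <- poisson_coef(data$x, data$y)
  if (jitter_sd > 0) beta <- beta + stats::rnorm(length(beta), 0, jitter_sd)
  emax <- max(data$x %*% beta)
  if (emax > 0 || (emax == 0 && any(data$y == 0L))) {
    beta[1L] <- beta[1L] - (emax + delta)
  }
  st <- list(beta = beta)
  if (!is.null(data$cluster)) {
    st$u <- rep(0, length(data$cluster_labels))
    st$sigma_u <- 0.5
  }
  if (!constraint_ok(st$beta, data, u = st$u)) {
    stop("could not find a starting state satisfying the restriction theta_i <= 1")
  }
  st
}

# Poisson GLM coefficients with a safe fallback for degenerate outcomes.
poisson_coef <- function(x, y) {
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(x, y, family = stats::poisson())),
    error = function(e) NULL
  )
  if (!is.null(fit) && all(is.finite(fit$coefficients))) {
    return(unname(fit$coefficients))
  }
  c(log(max(mean(y), 1 / (2 * length(y)))), rep(0, ncol(x) - 1L))
}

#' Run multiple constrained MCMC chains
#'
#' Independent chains from distinct sub-seeds, component-wise adaptive
#' random-walk Metropolis. Proposal scales adapt toward
#' `settings$target_accept` by Robbins-Monro updates during burn-in only
#' and are frozen afterwards, so the retained portion of each chain is a
#' fixed-kernel Markov chain. Every retained draw satisfies
#' [constraint_ok()] by construction.
#'
#' @inheritParams log_posterior
#' @param settings A [chain_settings()].
#' @return An object of class `"rr_chains"`: list with `draws` (one
#'   retained-draws matrix per chain, columns named per parameter),
#'   `acceptance` (post-burn-in acceptance rate per parameter and chain),
#'   `rhat` (Gelman-Rubin statistic per parameter), `settings`,
#'   `param_names`, `family`, `mixed`, and `final_states`.
#' @export
run_chains <- function(data, prior = prior_spec(), settings = chain_settings()) {
  stopifnot(inherits(data, "rr_data"), inherits(settings, "rr_chain_settings"))
  ctx <- make_ctx(data, prior)
  mn <- ctx$family == "multinomial"
  p1 <- ncol(data$x)
  if (mn) {
    param_names <- as.vector(t(outer(
      seq_len(data$J - 1L), colnames(data$x),
      function(j, nm) paste0("cat", j, ":", nm)
    )))
  } else {
    param_names <- colnames(data$x)
    if (ctx$mixed) {
      param_names <- c(param_names, paste0("u[", data$cluster_labels, "]"), "sigma_u")
    }
  }
  K <- length(param_names)
  n_keep <- (settings$n_iter - settings$burn_in) %/% settings$thin
  set.seed(settings$seed)
  sub_seeds <- sample.int(2147483646L, settings$n_chains)

  draws <- vector("list", settings$n_chains)
  acc <- matrix(0, K, settings$n_chains, dimnames = list(param_names, NULL))
  finals <- vector("list", settings$n_chains)
  sweep_fun <- if (mn) sweep_multinomial else sweep_binary

  for (ch in seq_len(settings$n_chains)) {
    set.seed(sub_seeds[ch])
    st <- initialize_state(data, prior, jitter_sd = if (ch == 1L) 0 else 0.02)
    st <- cache_state(as_rr_state(st), ctx)
    if (!is.finite(st$ll)) stop("initial state has zero likelihood")
    log_scales <- rep(log(0.1), K)
    if (!mn && ctx$mixed) log_scales[(p1 + 1L):K] <- log(0.4)
    out <- matrix(NA_real_, n_keep, K, dimnames = list(NULL, param_names))
    acc_sum <- numeric(K)
    n_after <- 0L
    row <- 0L
    for (it in seq_len(settings$n_iter)) {
      res <- sweep_fun(st, ctx, exp(log_scales))
      st <- res$state
      if (it <= settings$burn_in) {
        gam <- (it + 10)^-0.6
        log_scales <- pmin(pmax(log_scales + gam * (res$alpha - settings$target_accept), -12), 4)
      } else {
        acc_sum <- acc_sum + res$alpha
        n_after <- n_after + 1L
        if ((it - settings$burn_in) %% settings$thin == 0L) {
          row <- row + 1L
          out[row, ] <- if (mn) as.vector(t(st$B)) else c(st$beta, st$u, st$sigma_u)
        }
      }
      if (it %% 1000L == 0L) st <- cache_state(st, ctx) # refresh cached eta/ll
    }
    draws[[ch]] <- out[seq_len(row), , drop = FALSE]
    acc[, ch] <- acc_sum / max(n_after, 1L)
    finals[[ch]] <- st
  }

  rhat <- vapply(seq_len(K), function(k) {
    gelman_rubin(lapply(draws, function(d) d[, k]))
  }, numeric(1))
  names(rhat) <- param_names

  structure(
    list(
      draws = draws, acceptance = acc, rhat = rhat, settings = settings,
      param_names = param_names, family = ctx$family,
      mixed = isTRUE(ctx$mixed), final_states = finals,
      coef_names = if (mn) param_names else colnames(data$x)
    ),
    class = "rr_chains"
  )
}

#' @export
print.rr_chains <- function(x, ...) {
  cat("<rr_chains> ", length(x$draws), " chains x ", nrow(x$draws[[1]]),
    " retained draws, ", length(x$param_names), " parameters\n",
    sep = ""
  )
  cat("  max R-hat: ", format(max(x$rhat), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Pool retained draws across chains
#'
#' @param chains An `rr_chains` object.
#' @param parameter Optional parameter name; default returns the full matrix.
#' @return A numeric vector (one parameter) or matrix (all parameters).
#' @export
pooled_draws <- function(chains, parameter = NULL) {
  m <- do.call(rbind, chains$draws)
  if (is.null(parameter)) {
    return(m)
  }
  if (!parameter %in% colnames(m)) stop("unknown parameter: ", parameter)
  m[, parameter]
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The classic between/within-chain variance diagnostic (no
#' rank-normalization, no chain splitting): with m chains of length n,
#' `R-hat = sqrt(((n-1)/n * W + B/n) / W)` where `W` is the mean
#' within-chain variance and `B/n` the variance of the chain means.
#' Values near 1 indicate the chains have mixed.
#'
#' @param chains A list of >= 2 equal-length numeric vectors (length
#'   >= 10), or a matrix with one chain per column.
#' @return The scalar R-hat (>= ~1; slightly below 1 is possible by
#'   sampling noise).
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  m <- length(chains)
  if (m < 2) stop("Gelman-Rubin diagnostic needs at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("chains must have equal length")
  if (n < 10) stop("chains must have length >= 10")
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  W <- mean(vars)
  Bn <- stats::var(means) # = B/n
  if (W <= 0) {
    return(if (Bn <= 0) 1 else Inf)
  }
  sqrt(((n - 1) / n * W + Bn) / W)
}

#' Serialize retained draws and run metadata
#'
#' Writes a long-format CSV (`chain, iteration, parameter, value`) and a
#' JSON sidecar holding the settings, acceptance rates and R-hat values.
#'
#' @param chains An `rr_chains` object.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_chains <- function(chains, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(chains, "rr_chains"))
  if (!is.null(csv_path)) {
    long <- do.call(rbind, lapply(seq_along(chains$draws), function(ch) {
      d <- chains$draws[[ch]]
      data.frame(
        chain = ch, iteration = rep(seq_len(nrow(d)), ncol(d)),
        parameter = rep(colnames(d), each = nrow(d)), value = as.vector(d)
      )
    }))
    utils::write.csv(long, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    meta <- list(
      settings = unclass(chains$settings),
      acceptance = as.data.frame(t(chains$acceptance)),
      rhat = as.list(chains$rhat),
      family = chains$family, mixed = chains$mixed
    )
    jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(csv_path, json_path))
}
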