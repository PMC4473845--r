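# Shared fixtures and reduced MCMC settings used across the test files.
# MCMC settings here are deliberately small; the properties checked are
# statistical (recovery, coverage, oracle agreement), not draw-for-draw.

quick_settings <- function(seed, n_chains = 2, n_iter = 1500, burn_in = 500, thin = 1) {
  chain_settings(
    n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
    thin = thin, seed = seed
  )
}

intercept_only_data <- function(n, k) {
  rr_data(
    rep(c(1L, 0L), c(k, n - k)),
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  )
}

# independent binary scenario with one binary exposure (true RR = rr)
binary_scenario <- function(n, seed, p0 = 0.2, rr = 1.5, prevalence = 0.5) {
  scenario_spec(
    family = "binomial", beta = c(log(p0), log(rr)), n = n,
    covariates = list(list(type = "binary", prevalence = prevalence)),
    seed = seed
  )
}

clustered_scenario <- function(m, size, seed, p0 = 0.2, rr = 1.5, sigma_u = 0.3) {
  scenario_spec(
    family = "clustered", beta = c(log(p0), log(rr)),
    n_clusters = m, cluster_size = size, sigma_u = sigma_u,
    covariates = list(list(type = "binary", prevalence = 0.5)),
    seed = seed
  )
}

# small deterministic design for conformability / density checks
toy_binary_data <- function() {
  x <- cbind(1, c(0, 0, 1, 1, 0.5, 0.25))
  rr_data(c(1L, 0L, 1L, 0L, 1L, 0L), x)
}

# brute-force multinomial log-likelihood by per-row enumeration
mn_loglik_bruteforce <- function(B, data) {
  total <- 0
  for (i in seq_len(data$n)) {
    probs <- numeric(data$J)
    for (j in seq_len(data$J - 1L)) {
      probs[j + 1L] <- exp(sum(data$x[i, ] * B[j, ]))
    }
    probs[1L] <- 1 - sum(probs[-1L])
    total <- total + log(probs[data$y[i] + 1L])
  }
  total
}
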