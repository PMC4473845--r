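test_that("same seed gives bit-identical chains and the retained length is as configured", {
  d <- gen_independent_binary(binary_scenario(120, seed = 5))
  s <- quick_settings(seed = 31, n_iter = 1200, burn_in = 200)
  c1 <- run_chains(d, settings = s)
  c2 <- run_chains(d, settings = s)
  expect_identical(c1$draws, c2$draws)
  expect_identical(c1$acceptance, c2$acceptance)
  expect_equal(nrow(c1$draws[[1]]), (1200 - 200) %/% 1)

  s2 <- chain_settings(n_chains = 2, n_iter = 2300, burn_in = 250, thin = 4, seed = 9)
  c3 <- run_chains(d, settings = s2)
  expect_equal(vapply(c3$draws, nrow, integer(1)), rep((2300 - 250) %/% 4, 2))
})

test_that("every retained draw satisfies the probability constraints", {
  # independent binary
  d <- gen_independent_binary(binary_scenario(150, seed = 2))
  cs <- run_chains(d, settings = quick_settings(seed = 12, n_iter = 1100, burn_in = 100))
  for (dr in cs$draws) {
    ok <- apply(dr, 1, function(b) constraint_ok(b, d))
    expect_true(all(ok))
  }
  # mixed: check at each draw's own cluster effects
  dc <- gen_clustered_binary(clustered_scenario(15, 10, seed = 3))
  csm <- run_chains(dc, settings = quick_settings(seed = 4, n_iter = 1100, burn_in = 100))
  p1 <- ncol(dc$x)
  m <- length(dc$cluster_labels)
  for (dr in csm$draws) {
    ok <- apply(dr, 1, function(v) {
      constraint_ok(v[1:p1], dc, u = v[(p1 + 1):(p1 + m)])
    })
    expect_true(all(ok))
    expect_true(all(dr[, "sigma_u"] >= 0.01 & dr[, "sigma_u"] <= 100))
  }
  # multinomial
  dm <- gen_multinomial(scenario_spec("multinomial",
    B = matrix(c(log(0.3), log(0.2)), 2, 1), n = 120, seed = 6
  ))
  csn <- run_chains(dm, settings = quick_settings(seed = 5, n_iter = 1100, burn_in = 100))
  for (dr in csn$draws) {
    ok <- apply(dr, 1, function(v) constraint_ok(matrix(v, 2, 1, byrow = TRUE), dm))
    expect_true(all(ok))
  }
})

test_that("a vanishing proposal scale accepts everything and barely moves the state", {
  d <- gen_independent_binary(binary_scenario(60, seed = 8))
  st <- initialize_state(d)
  cur <- st$beta
  set.seed(99)
  for (i in 1:50) cur <- metropolis_sweep(cur, d, scales = rep(1e-8, 2))
  expect_equal(cur, st$beta, tolerance = 1e-5)
  expect_false(identical(cur, st$beta)) # it did move, just microscopically
})

test_that("metropolis_sweep rejects an initially invalid state", {
  d <- toy_binary_data()
  expect_error(metropolis_sweep(c(0.5, 0), d, scales = c(0.1, 0.1)), "restriction")
})

test_that("the incremental fast path stays consistent with fresh density evaluation", {
  dc <- gen_clustered_binary(clustered_scenario(12, 8, seed = 21))
  cs <- run_chains(dc, settings = quick_settings(seed = 13, n_iter = 1050, burn_in = 50))
  for (st in cs$final_states) {
    expect_equal(st$ll, logbin_loglik(st$beta, dc, u = st$u), tolerance = 1e-8)
  }
  dm <- gen_multinomial(scenario_spec("multinomial",
    B = matrix(c(log(0.25), 0.2, log(0.2), -0.1), 2, 2, byrow = TRUE),
    n = 100, covariates = list(list(type = "binary", prevalence = 0.4)), seed = 22
  ))
  csm <- run_chains(dm, settings = quick_settings(seed = 14, n_iter = 1050, burn_in = 50))
  for (st in csm$final_states) {
    expect_equal(st$ll, logmultinomial_loglik(st$B, dm), tolerance = 1e-8)
  }
})

test_that("adapted acceptance rates land in a sensible band", {
  d <- gen_independent_binary(binary_scenario(200, seed = 17))
  cs <- run_chains(d, settings = quick_settings(seed = 18, n_iter = 2000, burn_in = 1000))
  expect_true(all(cs$acceptance >= 0.15 & cs$acceptance <= 0.5))
})

test_that("different seeds mix: R-hat below 1.1 on a fixture problem", {
  d <- kerry_bland_trial()$data
  cs <- run_chains(d, settings = chain_settings(
    n_chains = 3, n_iter = 1500, burn_in = 500, thin = 1, seed = 27
  ))
  expect_true(all(cs$rhat < 1.1))
})

test_that("Gelman-Rubin statistic behaves like a between/within variance ratio", {
  set.seed(123)
  a <- rnorm(1000)
  b <- rnorm(1000)
  expect_gt(gelman_rubin(list(a, b)), 0.99)
  expect_lt(gelman_rubin(list(a, b)), 1.05)
  expect_gt(gelman_rubin(list(a, b + 10)), 3)
  expect_equal(
    gelman_rubin(list(a, b)),
    gelman_rubin(list(a + 5, b + 5)),
    tolerance = 1e-12
  )
  expect_error(gelman_rubin(list(a)), "2 chains")
  expect_error(gelman_rubin(list(a, b[1:500])), "equal length")
})

test_that("initializer returns a valid state, shifting the intercept only when needed", {
  # Poisson start already valid: kept as-is
  d <- gen_independent_binary(binary_scenario(300, seed = 33, p0 = 0.1))
  pf <- fit_poisson_robust(d)
  st <- initialize_state(d)
  if (constraint_ok(coef(pf), d)) expect_equal(st$beta, unname(coef(pf)))
  expect_true(constraint_ok(st$beta, d))

  # high-risk data push the Poisson fit out of bounds: intercept is shifted
  # down so the largest fitted probability is exp(-delta)
  set.seed(34)
  xh <- cbind(1, runif(80, 0, 1))
  yh <- rbinom(80, 1, pmin(0.95, 0.55 + 0.4 * xh[, 2]))
  dh <- rr_data(yh, xh)
  if (!constraint_ok(unname(coef(fit_poisson_robust(dh))), dh)) {
    sth <- initialize_state(dh)
    expect_true(constraint_ok(sth$beta, dh))
    expect_equal(max(dh$x %*% sth$beta), -0.01, tolerance = 1e-9)
  }

  # intercept-only: starts at log(mean(y))
  d0 <- intercept_only_data(50, 20)
  expect_equal(initialize_state(d0)$beta, log(0.4))

  # mixed defaults
  dc <- gen_clustered_binary(clustered_scenario(10, 6, seed = 35))
  stm <- initialize_state(dc)
  expect_equal(stm$u, rep(0, 10))
  expect_equal(stm$sigma_u, 0.5)
})

test_that("settings validation enforces the estimation minimum", {
  expect_error(chain_settings(n_chains = 1), "2 chains")
  expect_error(chain_settings(n_iter = 1000, burn_in = 900, thin = 1), "1000")
  expect_error(chain_settings(thin = 0), "thin")
  expect_silent(chain_settings(n_chains = 3, n_iter = 100000, burn_in = 50000, thin = 100))
})

test_that("chain serialization writes the draws table and metadata sidecar", {
  d <- gen_independent_binary(binary_scenario(80, seed = 41))
  cs <- run_chains(d, settings = quick_settings(seed = 42, n_iter = 1100, burn_in = 100))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_chains(cs, csv_path = csv, json_path = js)
  long <- read.csv(csv)
  expect_setequal(names(long), c("chain", "iteration", "parameter", "value"))
  expect_equal(nrow(long), 2 * 1000 * 2)
  meta <- jsonlite::read_json(js)
  expect_equal(meta$settings$seed, 42)
  expect_named(meta$rhat, cs$param_names)
})
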