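test_that("linear predictor is x'beta plus the row's cluster effect", {
  d <- toy_binary_data()
  expect_equal(linear_predictor(c(0, 0), d), rep(0, 6))

  # trial-scale arithmetic: intercept -0.315, intervention effect 0.092
  d1 <- rr_data(1L, matrix(c(1, 1), 1, 2))
  expect_equal(linear_predictor(c(-0.315, 0.092), d1), -0.223)

  dc <- rr_data(c(1L, 0L), cbind(1, c(3, 3)), cluster = c("a", "a"))
  expect_equal(linear_predictor(c(1, 2), dc, u = 0.5)[1], 7.5)

  expect_error(linear_predictor(c(1, 2, 3), d), "conform|columns|length")
  expect_error(linear_predictor(c(1, 2), d, u = 0.5), "no clusters")
  expect_error(linear_predictor(c(1, 2), dc, u = c(0.5, 0.1)), "clusters")
})

test_that("probabilities exponentiate eta and fill the reference by complement", {
  d <- toy_binary_data()
  expect_equal(rr_probabilities(c(log(0.5), 0), d), rep(0.5, 6))

  d2 <- rr_data(c(1L, 1L), cbind(1, c(0, 1)))
  th <- rr_probabilities(c(-0.315, 0.092), d2)
  expect_equal(th, exp(c(-0.315, -0.223)))
  # close to the trial's printed group proportions 72.51% / 79.48%
  expect_equal(th, c(0.7251, 0.7948), tolerance = 1e-2)

  # polytomous: three categories each at 0.2 leave 0.4 for the reference
  dm <- rr_data(c(0L, 1L, 2L, 3L), matrix(1, 4, 1), family = "multinomial")
  B <- matrix(log(0.2), 3, 1)
  P <- rr_probabilities(B, dm)
  expect_equal(unname(P[, 1]), rep(0.4, 4))
  expect_equal(rowSums(P), rep(1, 4))
})

test_that("constraint allows the boundary and rejects invalid probabilities", {
  d <- toy_binary_data()
  expect_true(constraint_ok(c(0, 0), d)) # theta = 1 exactly: allowed
  expect_false(constraint_ok(c(0.1, 0), d))

  trial <- kerry_bland_trial()$data
  expect_true(constraint_ok(c(-0.314, 0.089), trial)) # max eta = -0.225 < 0

  dm <- rr_data(c(0L, 1L), matrix(1, 2, 1), family = "multinomial")
  expect_true(constraint_ok(matrix(log(0.5), 1, 1), dm))
  expect_false(constraint_ok(matrix(log(1.2), 1, 1), dm))
  # two categories at 0.6 each: each theta <= 1 but the complement is negative
  dm3 <- rr_data(c(0L, 1L, 2L), matrix(1, 3, 1), family = "multinomial")
  expect_false(constraint_ok(matrix(log(0.6), 2, 1), dm3))
})

test_that("log-binomial likelihood matches direct cell arithmetic and guards the support", {
  d <- intercept_only_data(2, 1)
  expect_equal(logbin_loglik(log(0.5), d), 2 * log(0.5))

  # expanded trial rows at the crude per-arm probabilities equal the
  # saturated 2x2 binomial log-likelihood summed over the four cells
  trial <- kerry_bland_trial()$data
  p0 <- 509 / 702
  rr <- (341 / 429) / p0
  cells <- 341 * log(p0 * rr) + (429 - 341) * log(1 - p0 * rr) +
    509 * log(p0) + (702 - 509) * log(1 - p0)
  expect_equal(logbin_loglik(c(log(p0), log(rr)), trial), cells, tolerance = 1e-12)

  expect_identical(logbin_loglik(c(0.2, 0), toy_binary_data()), -Inf)
  # theta = 1 with an observed zero is a log-zero term
  expect_identical(logbin_loglik(0, intercept_only_data(3, 2)), -Inf)
  expect_identical(logbin_loglik(0, intercept_only_data(3, 3)), 0)

  dm <- rr_data(c(0L, 1L, 2L), matrix(1, 3, 1), family = "multinomial")
  expect_error(logbin_loglik(c(0, 0), dm), "binomial")
})

test_that("log-multinomial likelihood agrees with brute-force enumeration and J=2 reduces to log-binomial", {
  set.seed(42)
  x <- cbind(1, runif(6, -1, 1))
  y <- c(0L, 1L, 2L, 0L, 2L, 1L)
  dm <- rr_data(y, x, family = "multinomial")
  B <- matrix(c(log(0.25), 0.1, log(0.3), -0.2), 2, 2, byrow = TRUE)
  expect_true(constraint_ok(B, dm))
  expect_equal(logmultinomial_loglik(B, dm), mn_loglik_bruteforce(B, dm), tolerance = 1e-12)

  # equal probability 1/J for every category: n log(1/J)
  dm4 <- rr_data(rep(0:3, 2), matrix(1, 8, 1), family = "multinomial")
  B4 <- matrix(log(0.25), 3, 1)
  expect_equal(logmultinomial_loglik(B4, dm4), 8 * log(0.25))

  # J = 2: recode "event" as category 1 and compare with the binary model
  for (s in 1:5) {
    set.seed(s)
    xb <- cbind(1, rbinom(10, 1, 0.5))
    yb <- rbinom(10, 1, 0.4)
    beta <- c(log(0.3), runif(1, -0.3, 0.3))
    db <- rr_data(yb, xb, family = "binomial")
    dm2 <- rr_data(yb, xb, family = "multinomial")
    if (!constraint_ok(beta, db)) next
    expect_equal(
      logmultinomial_loglik(matrix(beta, 1), dm2),
      logbin_loglik(beta, db),
      tolerance = 1e-12
    )
  }

  expect_error(logmultinomial_loglik(B, rr_data(c(0L, 3L), matrix(1, 2, 1), family = "multinomial")))
})

test_that("priors: independent normals plus a uniform for the random-effect SD", {
  pr <- prior_spec()
  expect_equal(log_prior(0, pr), -0.5 * log(2 * pi * 1e6))
  expect_identical(
    log_prior(list(beta = 0, u = 0, sigma_u = 0.005), pr),
    -Inf
  )
  st <- list(beta = c(0.5, -1, 2), sigma_u = 1)
  expect_equal(
    log_prior(st, pr),
    sum(dnorm(c(0.5, -1, 2), 0, 1000, log = TRUE)) + log(1 / 99.99)
  )
  # the multinomial coefficient matrix gets the same prior entry-wise
  B <- matrix(c(-1, 0.2, -2, 0.1), 2, 2)
  expect_equal(log_prior(B, pr), sum(dnorm(as.numeric(B), 0, 1000, log = TRUE)))
  expect_error(prior_spec(coef_var = -1))
  expect_error(prior_spec(sd_lower = 2, sd_upper = 1))
})

test_that("log posterior composes likelihood, prior and cluster-effect density", {
  d <- toy_binary_data()
  pr <- prior_spec()
  expect_identical(log_posterior(c(0.2, 0), d, pr), -Inf)

  dc <- rr_data(c(1L, 0L, 1L, 0L), cbind(1, c(0, 0, 1, 1)), cluster = c(1, 1, 2, 2))
  st <- list(beta = c(log(0.4), 0.1), u = c(0, 0), sigma_u = 0.5)
  manual <- logbin_loglik(st$beta, dc, u = st$u) +
    log_prior(st, pr) + 2 * dnorm(0, 0, 0.5, log = TRUE)
  expect_equal(log_posterior(st, dc, pr), manual, tolerance = 1e-12)

  # row permutation within the cluster structure leaves the posterior unchanged
  set.seed(7)
  perm <- sample(4)
  dp <- rr_data(dc$y[perm], dc$x[perm, ], cluster = dc$cluster[perm])
  expect_equal(log_posterior(st, dp, pr), log_posterior(st, dc, pr), tolerance = 1e-10)
})

test_that("valid states give probability vectors in [0,1] that sum to one", {
  set.seed(11)
  for (rep in 1:20) {
    x <- cbind(1, runif(8, -1, 1))
    dm <- rr_data(sample(0:2, 8, replace = TRUE), x, family = "multinomial")
    B <- matrix(rnorm(4, -1.5, 0.4), 2, 2)
    if (!constraint_ok(B, dm)) next
    P <- rr_probabilities(B, dm)
    expect_true(all(P >= 0))
    expect_equal(rowSums(P), rep(1, 8), tolerance = 1e-12)
  }
})

test_that("datasets round-trip through the CSV dialect", {
  dc <- rr_data(c(1L, 0L, 1L), cbind(1, c(0.1, 0.2, 0.3), c(1, 0, 1)),
    cluster = c("a", "a", "b")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_rr_data(dc, path)
  back <- read_rr_data(path)
  expect_equal(back$y, dc$y)
  expect_equal(unname(back$x), unname(dc$x))
  expect_equal(back$cluster, dc$cluster)
  expect_equal(back$cluster_labels, dc$cluster_labels)
})

test_that("dataset validation rejects malformed input", {
  expect_error(rr_data(c(1, NA), matrix(1, 2, 1)), "missing")
  expect_error(rr_data(c(1, 0), matrix(2, 2, 1)), "intercept")
  expect_error(rr_data(c(1, 0, 1), matrix(1, 2, 1)), "rows")
  expect_error(rr_data(c(1, 2), matrix(1, 2, 1), family = "binomial"), "0/1")
})
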