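#' Specify a synthetic-data scenario
#'
#' Describes one of the three data-generating settings the models target:
#' independent binary outcomes, random-intercept clustered binary
#' outcomes, or independent polytomous outcomes, each with a log link.
#' Covariate generators must have bounded support (`constant`, `binary`
#' or `uniform`) so that the valid-probability restriction can be checked
#' over the whole support before any data are drawn: a specification that
#' implies a probability above 1 anywhere on the support is rejected with
#' an error, never silently clipped.
#'
#' @param family `"binomial"`, `"clustered"` or `"multinomial"`.
#' @param beta True coefficient vector (intercept first), binary families.
#' @param B True (J-1) x (p+1) coefficient matrix, multinomial family.
#' @param n Number of observations (independent families).
#' @param n_clusters,cluster_size Number of clusters and common size (or
#'   a length-`n_clusters` vector of sizes), clustered family.
#' @param sigma_u Random-intercept standard deviation (clustered family).
#' @param covariates List of covariate generators, one per non-intercept
#'   design column, each a list with `type` in `c("constant", "binary",
#'   "uniform")` and fields `value`, `prevalence`, or `min`/`max`.
#' @param seed Mandatory integer seed.
#' @return An object of class `"rr_scenario"`.
#' @export
scenario_spec <- function(family = c("binomial", "clustered", "multinomial"),
                          beta = NULL, B = NULL, n = NULL,
                          n_clusters = NULL, cluster_size = NULL, sigma_u = 0,
                          covariates = list(), seed) {
  family <- match.arg(family)
  if (missing(seed)) stop("a seed is mandatory for scenario reproducibility")
  for (cv in covariates) {
    if (!is.list(cv) || !cv$type %in% c("constant", "binary", "uniform")) {
      stop("each covariate generator must be constant, binary or uniform")
    }
  }
  spec <- structure(
    list(
      family = family, beta = beta, B = if (!is.null(B)) as.matrix(B),
      n = n, n_clusters = n_clusters, cluster_size = cluster_size,
      sigma_u = sigma_u, covariates = covariates, seed = as.integer(seed)
    ),
    class = "rr_scenario"
  )
  validate_scenario(spec)
  spec
}

# Worst-case linear-predictor contribution of one covariate over its support.
cov_bounds <- function(cv) {
  switch(cv$type,
    constant = c(cv$value, cv$value),
    binary = c(0, 1),
    uniform = c(cv$min, cv$max)
  )
}

max_eta_support <- function(coefs, covariates) {
  # coefs: intercept + one coefficient per covariate
  if (length(coefs) != length(covariates) + 1L) {
    stop("coefficient length does not match the covariate list (+1 intercept)")
  }
  s <- coefs[1L]
  for (i in seq_along(covariates)) {
    b <- cov_bounds(covariates[[i]])
    s <- s + max(coefs[i + 1L] * b)
  }
  s
}

validate_scenario <- function(spec) {
  if (spec$family == "multinomial") {
    if (is.null(spec$B) || is.null(spec$n)) stop("multinomial scenarios need B and n")
    # conservative: sum of per-category suprema must stay below 1
    tot <- sum(apply(spec$B, 1, function(b) exp(max_eta_support(b, spec$covariates))))
    if (tot > 1) {
      stop(
        "scenario implies total non-reference probability ", signif(tot, 4),
        " > 1 somewhere on the covariate support"
      )
    }
  } else {
    if (is.null(spec$beta)) stop("binary scenarios need beta")
    if (spec$family == "binomial" && is.null(spec$n)) stop("need n")
    if (spec$family == "clustered" &&
      (is.null(spec$n_clusters) || is.null(spec$cluster_size))) {
      stop("clustered scenarios need n_clusters and cluster_size")
    }
    emax <- max_eta_support(spec$beta, spec$covariates)
    if (emax > 0) {
      stop(
        "scenario implies probability exp(", signif(emax, 4),
        ") > 1 somewhere on the covariate support"
      )
    }
  }
  invisible(spec)
}

draw_covariates <- function(covariates, n) {
  if (!length(covariates)) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  cols <- lapply(covariates, function(cv) {
    switch(cv$type,
      constant = rep(cv$value, n),
      binary = stats::rbinom(n, 1, cv$prevalence),
      uniform = stats::runif(n, cv$min, cv$max)
    )
  })
  x <- cbind(1, do.call(cbind, cols))
  colnames(x) <- c("(Intercept)", if (!is.null(names(covariates)) && all(nzchar(names(covariates)))) {
    names(covariates)
  } else {
    paste0("x", seq_along(covariates))
  })
  x
}

#' Generate independent binary data from a log-binomial model
#'
#' Covariates are drawn per the scenario, then
#' `y_i ~ Bernoulli(exp(x_i' beta))`. Reproducible from the scenario seed.
#'
#' @param spec An [scenario_spec()] with `family = "binomial"`.
#' @return An [rr_data()] object.
#' @export
gen_independent_binary <- function(spec) {
  stopifnot(inherits(spec, "rr_scenario"), spec$family == "binomial")
  set.seed(spec$seed)
  x <- draw_covariates(spec$covariates, spec$n)
  theta <- exp(drop(x %*% spec$beta))
  rr_data(stats::rbinom(spec$n, 1, theta), x, family = "binomial")
}

#' Generate clustered binary data from a mixed-effects log-binomial model
#'
#' Cluster effects `u_i ~ N(0, sigma_u^2)` are drawn per cluster;
#' outcomes are `y_ij ~ Bernoulli(exp(x_ij' beta + u_i))`. A drawn `u_i`
#' that would push any probability in its cluster above 1 is rejected and
#' redrawn; the total number of rejections is reported as an attribute
#' (`"rejections"`), and a rejection rate above 50% aborts with advice to
#' lower the intercept or `sigma_u`, since by then the achieved
#' random-effect distribution is far from the nominal normal.
#'
#' @param spec An [scenario_spec()] with `family = "clustered"`.
#' @return An [rr_data()] object with clusters; attributes `"u"` (the
#'   accepted cluster effects) and `"rejections"`.
#' @export
gen_clustered_binary <- function(spec) {
  stopifnot(inherits(spec, "rr_scenario"), spec$family == "clustered")
  set.seed(spec$seed)
  m <- spec$n_clusters
  sizes <- if (length(spec$cluster_size) == 1L) rep(spec$cluster_size, m) else spec$cluster_size
  if (length(sizes) != m) stop("cluster_size must be scalar or length n_clusters")
  n <- sum(sizes)
  x <- draw_covariates(spec$covariates, n)
  cl <- rep(seq_len(m), sizes)
  eta_fix <- drop(x %*% spec$beta)
  emax <- vapply(split(eta_fix, cl), max, numeric(1))
  u <- numeric(m)
  rejections <- 0L
  if (spec$sigma_u > 0) {
    for (i in seq_len(m)) {
      repeat {
        ui <- stats::rnorm(1, 0, spec$sigma_u)
        if (emax[i] + ui <= 0) break
        rejections <- rejections + 1L
        if (rejections > 20L * m) break
      }
      u[i] <- ui
    }
  }
  if (rejections / (rejections + m) > 0.5) {
    stop(
      "more than 50% of cluster-effect draws violated theta <= 1; ",
      "use a smaller intercept or sigma_u"
    )
  }
  theta <- exp(eta_fix + u[cl])
  out <- rr_data(stats::rbinom(n, 1, theta), x, cluster = cl, family = "binomial")
  attr(out, "u") <- u
  attr(out, "rejections") <- rejections
  out
}

#' Generate independent polytomous data from a log-multinomial model
#'
#' Per-row category probabilities are `theta_ij = exp(x_i' B_j)` for the
#' non-reference categories, with the reference probability the
#' complement; `y_i` is drawn from that J-vector.
#'
#' @param spec An [scenario_spec()] with `family = "multinomial"`.
#' @return An [rr_data()] object with a polytomous outcome (0 = reference).
#' @export
gen_multinomial <- function(spec) {
  stopifnot(inherits(spec, "rr_scenario"), spec$family == "multinomial")
  set.seed(spec$seed)
  x <- draw_covariates(spec$covariates, spec$n)
  Theta <- exp(x %*% t(spec$B))
  P <- cbind(1 - rowSums(Theta), Theta)
  y <- apply(P, 1, function(p) sample.int(ncol(P), 1, prob = p)) - 1L
  rr_data(y, x, family = "multinomial")
}

#' Read / write scenario files
#'
#' Flat key-value config (YAML-free): `key = value` lines; covariates as
#' `covariate.<i>.<field>`. Provided so scenarios can be version-
#' controlled alongside results.
#'
#' @param spec An `rr_scenario`; `path` a file path.
#' @return `read_scenario()` returns an `rr_scenario`.
#' @export
write_scenario <- function(spec, path) {
  stopifnot(inherits(spec, "rr_scenario"))
  kv <- c(
    paste("family =", spec$family),
    if (!is.null(spec$beta)) paste("beta =", paste(spec$beta, collapse = ",")),
    if (!is.null(spec$B)) paste("B =", paste(apply(spec$B, 1, paste, collapse = ","), collapse = ";")),
    if (!is.null(spec$n)) paste("n =", spec$n),
    if (!is.null(spec$n_clusters)) paste("n_clusters =", spec$n_clusters),
    if (!is.null(spec$cluster_size)) paste("cluster_size =", paste(spec$cluster_size, collapse = ",")),
    paste("sigma_u =", spec$sigma_u),
    paste("seed =", spec$seed)
  )
  for (i in seq_along(spec$covariates)) {
    cv <- spec$covariates[[i]]
    for (f in names(cv)) kv <- c(kv, sprintf("covariate.%d.%s = %s", i, f, cv[[f]]))
  }
  writeLines(kv, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  lines <- grep("=", readLines(path), value = TRUE)
  keys <- trimws(sub("=.*", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  kv <- stats::setNames(as.list(vals), keys)
  num <- function(s) if (is.null(s)) NULL else as.numeric(strsplit(s, ",")[[1]])
  cov_keys <- grep("^covariate\\.", keys, value = TRUE)
  covariates <- list()
  if (length(cov_keys)) {
    idx <- sort(unique(as.integer(sub("^covariate\\.(\\d+)\\..*$", "\\1", cov_keys))))
    covariates <- lapply(idx, function(i) {
      fields <- grep(sprintf("^covariate\\.%d\\.", i), keys, value = TRUE)
      cv <- lapply(fields, function(k) {
        v <- kv[[k]]
        if (grepl("^type$", sub(sprintf("^covariate\\.%d\\.", i), "", k))) v else as.numeric(v)
      })
      names(cv) <- sub(sprintf("^covariate\\.%d\\.", i), "", fields)
      cv
    })
  }
  B <- if (!is.null(kv$B)) {
    do.call(rbind, lapply(strsplit(kv$B, ";")[[1]], function(r) as.numeric(strsplit(r, ",")[[1]])))
  }
  scenario_spec(
    family = kv$family, beta = num(kv$beta), B = B,
    n = if (!is.null(kv$n)) as.integer(kv$n),
    n_clusters = if (!is.null(kv$n_clusters)) as.integer(kv$n_clusters),
    cluster_size = if (!is.null(kv$cluster_size)) as.numeric(num(kv$cluster_size)),
    sigma_u = as.numeric(kv$sigma_u), covariates = covariates,
    seed = as.integer(kv$seed)
  )
}
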