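#' Cluster-randomized trial fixture: radiology-request guidelines
#'
#' The published 2x2 counts of a cluster-randomized trial in which
#' general practitioners were randomized to an intervention on requesting
#' radiology examinations: among 429 requests in the intervention arm,
#' 341 (79.48%) complied with the guidelines; among 702 control requests,
#' 509 (72.51%) were adequate. The fixture expands those counts to 1131
#' observation rows (outcome = compliance, covariate = intervention arm).
#'
#' The trial randomized 34 doctors, split equally between arms, but the
#' per-doctor patient counts were never published. With
#' `clusters = TRUE` a SYNTHETIC cluster scaffold is attached: patients
#' are assigned round-robin to 17 doctors per arm. This is NOT the real
#' allocation -- it carries essentially no between-doctor heterogeneity
#' -- and exists so clustered methods can be exercised end-to-end on
#' realistically shaped data. Quantities that depend on the true
#' allocation (notably the published GEE ICC of 0.010) are not
#' reproducible from it.
#'
#' @param clusters Attach the synthetic 34-doctor scaffold?
#' @return An object of class `"rr_fixture"`: list with `name`, `data`
#'   (an [rr_data()]), `counts`, `provenance`, `completeness`.
#' @export
kerry_bland_trial <- function(clusters = FALSE) {
  counts <- data.frame(
    arm = c("intervention", "control"),
    n = c(429L, 702L), events = c(341L, 509L),
    printed_pct = c(79.48, 72.51)
  )
  expand_arm <- function(n, k) c(rep(1L, k), rep(0L, n - k))
  y <- c(expand_arm(429L, 341L), expand_arm(702L, 509L))
  arm <- rep(c(1L, 0L), c(429L, 702L))
  x <- cbind(`(Intercept)` = 1, intervention = arm)
  cl <- NULL
  if (clusters) {
    # synthetic round-robin scaffold: 17 doctors per arm (34 total)
    cl <- integer(length(y))
    cl[arm == 1L] <- rep_len(1:17, 429L)
    cl[arm == 0L] <- rep_len(18:34, 702L)
  }
  structure(
    list(
      name = "kerry-bland",
      data = rr_data(y, x, cluster = cl, family = "binomial"),
      counts = counts,
      provenance = paste(
        "Published cluster-trial marginal counts: 341/429 compliant",
        "(intervention), 509/702 adequate (control); 34 doctors divided",
        "equally between arms, per-doctor counts unpublished."
      ),
      completeness = if (clusters) "aggregate-only + synthetic clusters" else "aggregate-only"
    ),
    class = "rr_fixture"
  )
}

#' Acute decompensated heart failure (ADHF) cohort margins
#'
#' Marginal numbers of a 65-patient cohort admitted for acute
#' decompensated heart failure, outcome death within three days of
#' admission: 15 of 65 died (23.1%). Row-level covariates (sodium,
#' septum, pulmonary artery systolic pressure) are not available, so the
#' fixture is aggregate-only; it carries the two published patient
#' covariate rows and the published robust-Poisson and Bayesian
#' coefficient vectors, which suffice for the probability-prediction
#' demonstrations (the unconstrained Poisson fit predicts probabilities
#' above 1 for both patients; the constrained model cannot).
#'
#' @return An `"rr_fixture"` (aggregate-only; no row-level `data`).
#' @export
adhf_margins <- function() {
  structure(
    list(
      name = "adhf",
      data = NULL,
      counts = data.frame(n = 65L, deaths = 15L, printed_pct = 23.1),
      patients = data.frame(
        `(Intercept)` = c(1, 1), septum = c(13, 12),
        sodium = c(136, 127), pasp = c(100, 53), check.names = FALSE
      ),
      # published point estimates (intercept, septum, sodium, PASP)
      poisson_coef = c(9.058, 0.229, -0.100, 0.018),
      mcmc_coef = c(7.742, 0.184, -0.088, 0.011),
      provenance = paste(
        "Published cohort margins: 65 ADHF patients, 15 deaths (23.1%);",
        "two patient covariate rows (13mm/136mEq/100mmHg and",
        "12mm/127mEq/53mmHg) and the tabulated robust-Poisson and",
        "Bayesian coefficient estimates."
      ),
      completeness = "aggregate-only"
    ),
    class = "rr_fixture"
  )
}

#' Birth-weight cohort category margins
#'
#' Marginal category counts of the classic 189-birth cohort with birth
#' weight cut into four categories: below 2.5 kg (59 births, 31.22%),
#' 2.5-3 kg (38, 20.10%), 3-4 kg (83, 43.92%, the reference category)
#' and 4 kg or more (9, 4.76%). Row-level covariates (mother's age,
#' smoking) are not vendored; the fixture is marginal-only, but the
#' marginals support an intercept-only log-multinomial fit, exposed via
#' `as_multinomial_data()`.
#'
#' @return An `"rr_fixture"` with `counts` and `labels`; category codes
#'   put the reference (3-4 kg) first as category 0.
#' @export
birthweight_margins <- function() {
  structure(
    list(
      name = "birthweight",
      data = NULL,
      counts = data.frame(
        label = c("3-4kg (ref)", "<2.5kg", "2.5-3kg", ">=4kg"),
        category = 0:3,
        count = c(83L, 59L, 38L, 9L),
        printed_pct = c(43.92, 31.22, 20.10, 4.76)
      ),
      provenance = paste(
        "Published marginal counts of the 189-birth cohort: 59 below 2.5kg",
        "(31.22%), 38 between 2.5 and 3kg (20.10%), 83 between 3 and 4kg",
        "(43.92%, reference), 9 of 4kg or more (4.76%). Row-level",
        "covariates not vendored."
      ),
      completeness = "aggregate-only"
    ),
    class = "rr_fixture"
  )
}

#' Expand a marginal-count fixture to an intercept-only dataset
#'
#' Aggregate-only fixtures refuse operations that need row-level
#' covariates, but their marginals fully determine an intercept-only
#' model; this expands the counts to observation rows for such fits.
#'
#' @param fixture An `rr_fixture` with a `counts` table.
#' @return An [rr_data()] object.
#' @export
as_multinomial_data <- function(fixture) {
  stopifnot(inherits(fixture, "rr_fixture"))
  if (fixture$name == "birthweight") {
    y <- rep(fixture$counts$category, fixture$counts$count)
    return(rr_data(y, matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)")),
      family = "multinomial"
    ))
  }
  if (fixture$name == "adhf") {
    y <- rep(c(1L, 0L), c(fixture$counts$deaths, fixture$counts$n - fixture$counts$deaths))
    return(rr_data(y, matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)")),
      family = "binomial"
    ))
  }
  stop("fixture '", fixture$name, "' has no marginal-count expansion")
}

#' @export
print.rr_fixture <- function(x, ...) {
  cat("<rr_fixture> ", x$name, " [", x$completeness, "]\n", sep = "")
  if (!is.null(x$counts)) print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Look up a fixture by name
#'
#' @param name One of `"kerry-bland"`, `"kerry-bland-clustered"`,
#'   `"adhf"`, `"birthweight"`.
#' @return An `rr_fixture`.
#' @export
get_fixture <- function(name) {
  switch(name,
    "kerry-bland" = kerry_bland_trial(clusters = FALSE),
    "kerry-bland-clustered" = kerry_bland_trial(clusters = TRUE),
    "adhf" = adhf_margins(),
    "birthweight" = birthweight_margins(),
    stop("unknown fixture: ", name)
  )
}
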