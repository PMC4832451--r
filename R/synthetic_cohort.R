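# Seeded cohort generators. All randomness is scoped through
# withr::with_seed, so the caller's RNG state is never touched and the
# same seed always yields the same cohort.

#' Default covariate specification for the synthetic logistic cohort
#'
#' Emulates the shape of a referred-for-angiography cohort: two continuous
#' covariates (standardised age and a standardised continuous marker) and a
#' binary sex indicator with prevalence 0.68. Paired with the default
#' coefficients of [generate_logistic_cohort()] it yields outcome
#' prevalence near 0.46.
#'
#' @return Named list of covariate specs, each `list(dist = "normal", mean,
#'   sd)` or `list(dist = "bernoulli", prob)`.
#' @export
default_covariate_spec <- function() {
  list(
    age    = list(dist = "normal", mean = 0, sd = 1),
    marker = list(dist = "normal", mean = 0, sd = 1),
    sex    = list(dist = "bernoulli", prob = 0.68)
  )
}

#' Generate a cohort from a known logistic model
#'
#' Draws covariates per spec, computes each patient's true risk through the
#' stated logistic model, and draws the binary outcome as
#' Bernoulli(true risk). Because the generating coefficients are known, the
#' output is a ground-truth fixture for parameter-recovery and calibration
#' checks.
#'
#' @param n_patients Cohort size (at least 2). Default 303, the size of the
#'   angiography-style cohort the defaults emulate.
#' @param covariates Named list of covariate specs; see
#'   [default_covariate_spec()].
#' @param intercept True intercept on the log-odds scale. The default
#'   -1.55, with the default covariates/coefficients, gives prevalence
#'   near 0.46.
#' @param coefficients Named numeric vector of true log-odds per covariate,
#'   names matching `covariates`. The default gives the binary sex covariate
#'   a log-odds of 1.98.
#' @param seed Integer seed; required.
#' @return List with `design` (data frame), `outcomes` (0/1), `true_risks`,
#'   `intercept`, `coefficients`, `seed`.
#' @examples
#' coh <- generate_logistic_cohort(n_patients = 100, seed = 7)
#' mean(coh$outcomes)
#' @export
generate_logistic_cohort <- function(n_patients = 303,
                                     covariates = default_covariate_spec(),
                                     intercept = -1.55,
                                     coefficients = c(age = 0.5, marker = 0.8, sex = 1.98),
                                     seed) {
  if (missing(seed)) stop("`seed` is required for reproducibility", call. = FALSE)
  if (n_patients < 2) stop("`n_patients` must be at least 2", call. = FALSE)
  if (!setequal(names(covariates), names(coefficients))) {
    stop("`coefficients` names must match `covariates` names", call. = FALSE)
  }
  for (nm in names(covariates)) {
    cs <- covariates[[nm]]
    if (identical(cs$dist, "normal")) {
      if (!is.finite(cs$sd) || cs$sd <= 0) {
        stop(sprintf("covariate '%s': sd must be > 0", nm), call. = FALSE)
      }
    } else if (identical(cs$dist, "bernoulli")) {
      if (!is.finite(cs$prob) || cs$prob <= 0 || cs$prob >= 1) {
        stop(sprintf("covariate '%s': prob must be in (0, 1)", nm), call. = FALSE)
      }
    } else {
      stop(sprintf("covariate '%s': dist must be 'normal' or 'bernoulli'", nm),
           call. = FALSE)
    }
  }

  withr::with_seed(seed, {
    design <- as.data.frame(lapply(covariates, function(cs) {
      switch(cs$dist,
             normal = stats::rnorm(n_patients, cs$mean, cs$sd),
             bernoulli = stats::rbinom(n_patients, 1, cs$prob))
    }))
    eta <- intercept +
      drop(as.matrix(design[, names(coefficients), drop = FALSE]) %*% coefficients)
    true_risks <- stats::plogis(eta)
    outcomes <- stats::rbinom(n_patients, 1, true_risks)
    list(design = design, outcomes = outcomes, true_risks = true_risks,
         intercept = intercept, coefficients = coefficients, seed = seed)
  })
}

#' Generate a binormal scored cohort with known theoretical AUC
#'
#' Case scores are drawn Normal(`mean_case`, `sd_case`) and control scores
#' Normal(`mean_control`, `sd_control`), then squashed to (0, 1) by the
#' inverse logit so they read as risks while every rank — and hence the
#' AUC — is preserved exactly. The closed-form binormal AUC,
#' `pnorm((mean_case - mean_control) / sqrt(sd_case^2 + sd_control^2))`, is
#' attached as the attribute `"theoretical_auc"`.
#'
#' @param n_cases,n_controls Group sizes, at least 1 each.
#' @param mean_case,mean_control Score means (raw scale).
#' @param sd_case,sd_control Score standard deviations, > 0.
#' @param seed Integer seed; required.
#' @return A [scored_cohort()] with attribute `theoretical_auc`.
#' @export
generate_binormal_cohort <- function(n_cases, n_controls,
                                     mean_case = 1, mean_control = 0,
                                     sd_case = 1, sd_control = 1, seed) {
  if (missing(seed)) stop("`seed` is required for reproducibility", call. = FALSE)
  stopifnot(n_cases >= 1, n_controls >= 1, sd_case > 0, sd_control > 0)
  scores <- withr::with_seed(seed, {
    c(stats::rnorm(n_cases, mean_case, sd_case),
      stats::rnorm(n_controls, mean_control, sd_control))
  })
  coh <- scored_cohort(stats::plogis(scores),
                       c(rep(1L, n_cases), rep(0L, n_controls)))
  attr(coh, "theoretical_auc") <-
    stats::pnorm((mean_case - mean_control) / sqrt(sd_case^2 + sd_control^2))
  coh
}
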