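#' Fit a multivariable logistic risk model
#'
#' Plain maximum-likelihood logistic regression, fitted by iteratively
#' reweighted least squares, yielding each patient's absolute risk of the
#' outcome. Covariates are used exactly as given — no standardisation, no
#' penalisation; categorical predictors must be pre-expanded to 0/1
#' indicator columns by the caller. Standard errors come from the inverse of
#' the observed information at the maximum.
#'
#' Non-convergence within `max_iter` iterations is reported (warning and
#' `converged = FALSE`), not hidden. Complete or quasi-complete separation —
#' coefficients diverging so that fitted risks pin to 0 or 1 — raises an
#' explicit error, since the maximum-likelihood estimate does not exist.
#'
#' @param design Data frame or numeric matrix of covariates, named columns,
#'   no missing values, each column with nonzero variance. May have zero
#'   columns (intercept-only model).
#' @param outcomes Binary 0/1 vector, one per row of `design`; both classes
#'   must be present.
#' @param tol Convergence tolerance on the relative change in deviance
#'   (default 1e-8).
#' @param max_iter Maximum IRLS iterations (default 50).
#'
#' @return Object of class `logistic_fit`: list with `intercept`,
#'   `coefficients` (named, log-odds per unit), `standard_errors` (including
#'   the intercept, first), `log_likelihood`, `converged`, `n_iterations`,
#'   `fitted_risks`, and `terms` (covariate names).
#' @examples
#' x <- data.frame(marker = c(0, 0, 0, 0, 1, 1, 1, 1))
#' y <- c(0, 0, 0, 1, 1, 1, 1, 0)
#' fit_logistic(x, y)
#' @export
fit_logistic <- function(design, outcomes, tol = 1e-8, max_iter = 50) {
  design <- as.data.frame(design)
  n <- nrow(design)
  if (n == 0L && length(outcomes) > 0L) {
    # zero-column design frames lose their row count; rebuild
    design <- as.data.frame(matrix(numeric(0), nrow = length(outcomes), ncol = 0))
    n <- length(outcomes)
  }
  if (length(outcomes) != n) {
    stop("`outcomes` must have one element per design row", call. = FALSE)
  }
  if (anyNA(design) || anyNA(outcomes)) {
    stop("missing values are not allowed", call. = FALSE)
  }
  if (!all(outcomes %in% c(0, 1))) {
    stop("outcomes must be coded 0/1", call. = FALSE)
  }
  if (length(unique(outcomes)) < 2L) {
    stop("both outcome classes must be present to fit a risk model", call. = FALSE)
  }
  p <- ncol(design)
  if (p > 0L) {
    if (!all(vapply(design, is.numeric, logical(1)))) {
      stop("all covariate columns must be numeric (expand categoricals to indicators)",
           call. = FALSE)
    }
    vars <- vapply(design, stats::var, numeric(1))
    if (any(vars == 0)) {
      stop(sprintf("covariate '%s' has zero variance", names(design)[vars == 0][1L]),
           call. = FALSE)
    }
    if (n < p + 1L) stop("need at least one more patient than parameters", call. = FALSE)
  }

  X <- cbind(`(Intercept)` = 1, as.matrix(design))
  fit <- withCallingHandlers(
    stats::glm.fit(X, outcomes, family = stats::binomial(),
                   control = stats::glm.control(epsilon = tol, maxit = max_iter)),
    warning = function(w) {
      # separation / non-convergence are re-reported below on our own terms
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )

  beta <- fit$coefficients
  eta <- drop(X %*% beta)
  mu <- fit$fitted.values
  boundary <- mu < 1e-10 | mu > 1 - 1e-10
  if (any(boundary) && max(abs(beta)) > 10) {
    stop("perfect separation detected: coefficients diverge and fitted risks pin to 0/1",
         call. = FALSE)
  }
  converged <- isTRUE(fit$converged)
  if (!converged) {
    warning("logistic fit did not converge within max_iter iterations", call. = FALSE)
  }

  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  se <- sqrt(diag(solve(info)))
  ll <- sum(outcomes * log(mu) + (1 - outcomes) * log1p(-mu))

  structure(
    list(intercept = unname(beta[1L]),
         coefficients = beta[-1L],
         standard_errors = se,
         log_likelihood = ll,
         converged = converged,
         n_iterations = fit$iter,
         fitted_risks = unname(mu),
         terms = colnames(X)[-1L]),
    class = "logistic_fit"
  )
}

#' Predict absolute risks from a fitted logistic model
#'
#' Applies the inverse-logit of the linear predictor,
#' `risk = plogis(intercept + sum(coef_j * x_j))`, to each row. Columns are
#' matched to the fit's covariates by name; a mismatch is an error, never a
#' silent reorder.
#'
#' @param fit A `logistic_fit` from [fit_logistic()].
#' @param design Data frame with exactly the covariate columns the fit used
#'   (any order; matched by name).
#' @return Numeric vector of absolute risks, strictly inside (0, 1).
#' @export
predict_risk <- function(fit, design) {
  stopifnot(inherits(fit, "logistic_fit"))
  design <- as.data.frame(design)
  if (length(fit$terms) == 0L) {
    n <- nrow(design)
    return(rep(stats::plogis(fit$intercept), n))
  }
  missing_cols <- setdiff(fit$terms, names(design))
  if (length(missing_cols)) {
    stop(sprintf("design is missing covariate column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  X <- as.matrix(design[, fit$terms, drop = FALSE])
  eta <- fit$intercept + drop(X %*% fit$coefficients)
  stats::plogis(eta)
}

# internal: score vector (gradient of the log-likelihood) at the estimate;
# used by tests to assert first-order optimality of every returned fit
logistic_score <- function(fit, design, outcomes) {
  design <- as.data.frame(design)
  X <- cbind(1, if (ncol(design)) as.matrix(design[, fit$terms, drop = FALSE]))
  mu <- stats::plogis(drop(X %*% c(fit$intercept, fit$coefficients)))
  drop(crossprod(X, outcomes - mu))
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic risk model: %d covariate(s), logLik %.3f, %s in %d iteration(s)\n",
              length(x$coefficients), x$log_likelihood,
              if (x$converged) "converged" else "NOT converged", x$n_iterations))
  if (length(x$coefficients)) {
    tab <- data.frame(coef = c(x$intercept, x$coefficients),
                      se = x$standard_errors,
                      row.names = c("(Intercept)", x$terms))
    print(round(tab, 4))
  } else {
    cat(sprintf("  intercept %.4f (SE %.4f)\n", x$intercept, x$standard_errors[1]))
  }
  invisible(x)
}
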