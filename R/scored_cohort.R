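#' Scored cohort: per-patient absolute risk plus binary outcome
#'
#' The universal input to the curve and metric functions. A scored cohort
#' pairs each patient's predicted absolute risk (a probability in \[0, 1\])
#' with the observed binary case indicator.
#'
#' @param risks Numeric vector of absolute risks in \[0, 1\].
#' @param outcomes Binary vector (0/1, or logical) of the same length;
#'   1 marks a case.
#' @param ids Optional patient identifiers, same length.
#'
#' @return An object of class `scored_cohort`: a data frame with columns
#'   `risk`, `outcome`, and (if supplied) `id`.
#' @examples
#' scored_cohort(c(0.9, 0.4, 0.1), c(1, 0, 0))
#' @export
scored_cohort <- function(risks, outcomes, ids = NULL) {
  risks <- as.numeric(risks)
  if (is.logical(outcomes)) outcomes <- as.integer(outcomes)
  outcomes <- as.numeric(outcomes)
  if (length(risks) != length(outcomes)) {
    stop("`risks` and `outcomes` must have the same length", call. = FALSE)
  }
  if (anyNA(risks) || anyNA(outcomes)) {
    stop("missing values are not allowed in a scored cohort", call. = FALSE)
  }
  if (any(risks < 0 | risks > 1)) {
    bad <- which(risks < 0 | risks > 1)[1L]
    stop(sprintf("risk outside [0, 1] at position %d (value %g)", bad, risks[bad]),
         call. = FALSE)
  }
  if (!all(outcomes %in% c(0, 1))) {
    bad <- which(!outcomes %in% c(0, 1))[1L]
    stop(sprintf("non-binary outcome at position %d (value %g)", bad, outcomes[bad]),
         call. = FALSE)
  }
  out <- data.frame(risk = risks, outcome = as.integer(outcomes))
  if (!is.null(ids)) {
    stopifnot(length(ids) == length(risks))
    out$id <- ids
  }
  class(out) <- c("scored_cohort", "data.frame")
  out
}

#' @export
print.scored_cohort <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Scored cohort: %d patients, %d cases (prevalence %.3f)\n",
              n, sum(x$outcome), mean(x$outcome)))
  invisible(x)
}

# internal: validate class balance, with optional relaxation for
# degenerate (single-class) cohorts
check_two_classes <- function(cohort, strict = TRUE) {
  n_cases <- sum(cohort$outcome == 1)
  n_controls <- sum(cohort$outcome == 0)
  if (n_cases == 0L) {
    stop("cohort contains no cases (outcome = 1); curve undefined", call. = FALSE)
  }
  if (strict && n_controls == 0L) {
    stop("cohort contains no non-cases (outcome = 0); use strict = FALSE to allow",
         call. = FALSE)
  }
  invisible(cohort)
}
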