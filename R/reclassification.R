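# Continuous (category-free) NRI and IDI for comparing two risk models on
# the same patients, from their standard definitions with asymptotic
# standard errors.

#' Continuous net reclassification improvement
#'
#' The category-free NRI between an old and a new risk model:
#' `[P(up | event) - P(down | event)] + [P(down | nonevent) - P(up | nonevent)]`,
#' where "up"/"down" mean any increase/decrease in predicted risk, however
#' small. A patient whose risk does not change counts in neither direction.
#' The asymptotic SE treats the event and non-event contributions as
#' independent binomial-style proportions; the CI is normal-theory and the
#' p-value two-sided.
#'
#' @param outcomes Binary 0/1 vector; both classes required.
#' @param risks_old,risks_new Risk vectors on the same patients.
#' @param conf Confidence level, default 0.95.
#' @return Object of class `reclassification_result`: `estimate` (in
#'   \[-2, 2\]), `se`, `ci_low`, `ci_high`, `p_value`, `n_events`,
#'   `n_nonevents`, `measure = "continuous NRI"`.
#' @examples
#' y <- c(1, 1, 1, 0, 0, 0)
#' old <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
#' new <- c(0.6, 0.7, 0.4, 0.4, 0.3, 0.6)
#' continuous_nri(y, old, new) # 2/3
#' @export
continuous_nri <- function(outcomes, risks_old, risks_new, conf = 0.95) {
  check_recl_inputs(outcomes, risks_old, risks_new)
  d <- risks_new - risks_old
  ev <- outcomes == 1
  n_e <- sum(ev); n_ne <- sum(!ev)
  p_up_e <- mean(d[ev] > 0);  p_down_e <- mean(d[ev] < 0)
  p_up_ne <- mean(d[!ev] > 0); p_down_ne <- mean(d[!ev] < 0)
  est <- (p_up_e - p_down_e) + (p_down_ne - p_up_ne)
  se <- sqrt((p_up_e + p_down_e - (p_up_e - p_down_e)^2) / n_e +
             (p_up_ne + p_down_ne - (p_down_ne - p_up_ne)^2) / n_ne)
  recl_result(est, se, n_e, n_ne, conf, "continuous NRI")
}

#' Integrated discrimination improvement
#'
#' The IDI is the change in discrimination slope between two models:
#' `(mean risk_new - mean risk_old | events) - (mean risk_new - mean
#' risk_old | nonevents)`. The SE combines the per-class sample variances of
#' the individual risk changes `d = risk_new - risk_old`:
#' `sqrt(var(d | events)/n_events + var(d | nonevents)/n_nonevents)`.
#'
#' @inheritParams continuous_nri
#' @return Object of class `reclassification_result` with
#'   `measure = "IDI"`; estimate bounded in \[-1, 1\].
#' @export
idi <- function(outcomes, risks_old, risks_new, conf = 0.95) {
  check_recl_inputs(outcomes, risks_old, risks_new)
  d <- risks_new - risks_old
  ev <- outcomes == 1
  n_e <- sum(ev); n_ne <- sum(!ev)
  est <- mean(d[ev]) - mean(d[!ev])
  se <- sqrt(stats::var(d[ev]) / n_e + stats::var(d[!ev]) / n_ne)
  recl_result(est, se, n_e, n_ne, conf, "IDI")
}

# shared input validation
check_recl_inputs <- function(outcomes, risks_old, risks_new) {
  if (length(outcomes) != length(risks_old) ||
      length(outcomes) != length(risks_new)) {
    stop("`outcomes`, `risks_old`, `risks_new` must have equal length", call. = FALSE)
  }
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be coded 0/1", call. = FALSE)
  if (length(unique(outcomes)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  invisible(NULL)
}

# shared result assembly; degenerate SE = 0 returns p = 1 for a null
# estimate (identical models) and NA-with-warning otherwise, since the
# normal test statistic is undefined
recl_result <- function(est, se, n_e, n_ne, conf, measure) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (is.na(se) || se == 0) {
    if (isTRUE(all.equal(est, 0))) {
      p <- 1
    } else {
      warning(sprintf("%s standard error is zero; p-value undefined", measure),
              call. = FALSE)
      p <- NA_real_
    }
    se <- if (is.na(se)) NA_real_ else 0
    ci <- c(est, est)
  } else {
    p <- 2 * stats::pnorm(-abs(est / se))
    ci <- est + c(-1, 1) * z * se
  }
  structure(
    list(estimate = est, se = se, ci_low = ci[1], ci_high = ci[2],
         p_value = p, n_events = n_e, n_nonevents = n_ne, measure = measure),
    class = "reclassification_result"
  )
}

#' @export
print.reclassification_result <- function(x, ...) {
  cat(sprintf("%s: %.3f (95%% CI %.3f to %.3f), P = %.3g; %d events / %d non-events\n",
              x$measure, x$estimate, x$ci_low, x$ci_high, x$p_value,
              x$n_events, x$n_nonevents))
  invisible(x)
}
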