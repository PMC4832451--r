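#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Patients are ranked by predicted risk and cut into risk-quantile groups
#' (patients sharing a risk value stay together, falling into the lower
#' group). Within each group, observed events are compared with expected
#' events (the sum of predicted risks); the statistic
#' `sum((O - E)^2 / E + ((n - O) - (n - E))^2 / (n - E))` is referred to a
#' chi-square distribution with `groups - 2` degrees of freedom.
#'
#' Applied to in-sample fitted risks — as is conventional — the test is
#' optimistic; it asks whether predicted probabilities track observed event
#' rates across the risk spectrum, not whether the model discriminates.
#'
#' @param cohort A [scored_cohort()]; risks must be strictly inside (0, 1).
#' @param n_groups Number of quantile groups, default 10. Ties at group
#'   boundaries can merge groups; degrees of freedom follow the realised
#'   group count.
#' @return Object of class `hoslem_result`: `chi_square`, `df`, `p_value`,
#'   and `groups` (a data frame with per-group `n`, `observed`, `expected`,
#'   `mean_risk`).
#' @examples
#' set.seed(42)
#' r <- runif(200, 0.05, 0.95)
#' hosmer_lemeshow(scored_cohort(r, rbinom(200, 1, r)))
#' @export
hosmer_lemeshow <- function(cohort, n_groups = 10) {
  if (!inherits(cohort, "scored_cohort")) {
    cohort <- scored_cohort(cohort$risk, cohort$outcome)
  }
  risk <- cohort$risk; outcome <- cohort$outcome
  n <- length(risk)
  if (n < 2 * n_groups) {
    stop("need at least 2 patients per group; reduce `n_groups`", call. = FALSE)
  }
  if (any(risk <= 0 | risk >= 1)) {
    stop("Hosmer-Lemeshow requires risks strictly inside (0, 1)", call. = FALSE)
  }

  # quantile breaks; right-closed intervals put boundary ties in the lower
  # group; duplicated breaks (heavy ties) merge groups
  br <- unique(stats::quantile(risk, probs = seq(0, 1, length.out = n_groups + 1)))
  grp <- cut(risk, breaks = br, include.lowest = TRUE, right = TRUE)

  obs <- tapply(outcome, grp, sum)
  exp_ev <- tapply(risk, grp, sum)
  n_g <- tapply(outcome, grp, length)
  mean_risk <- tapply(risk, grp, mean)
  keep <- !is.na(n_g)
  obs <- obs[keep]; exp_ev <- exp_ev[keep]; n_g <- n_g[keep]
  mean_risk <- mean_risk[keep]

  g <- length(n_g)
  exp_ne <- n_g - exp_ev
  if (any(exp_ev < .Machine$double.eps) || any(exp_ne < .Machine$double.eps)) {
    stop("a group has expected events or expected non-events of 0; use fewer groups",
         call. = FALSE)
  }
  chi2 <- sum((obs - exp_ev)^2 / exp_ev + ((n_g - obs) - exp_ne)^2 / exp_ne)
  df <- g - 2
  structure(
    list(chi_square = chi2, df = df,
         p_value = stats::pchisq(chi2, df = df, lower.tail = FALSE),
         groups = data.frame(n = as.vector(n_g),
                             observed = as.vector(obs),
                             expected = as.vector(exp_ev),
                             mean_risk = as.vector(mean_risk))),
    class = "hoslem_result"
  )
}

#' @export
print.hoslem_result <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: chi-square %.3f on %d df, P = %.3f (%d groups)\n",
              x$chi_square, x$df, x$p_value, nrow(x$groups)))
  invisible(x)
}
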