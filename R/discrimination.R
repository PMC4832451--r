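# ROC curves and C statistics with DeLong variance machinery, plus paired
# bootstrap comparison. The DeLong structural components are computed with
# midranks, which is algebraically identical to the O(cases x controls)
# pairwise psi-function definition (ties credited 1/2) but O(n log n).

# internal: DeLong structural components for one score vector.
# Returns auc, V10 (per-case components), V01 (per-control components).
delong_components <- function(risks, outcomes) {
  x <- risks[outcomes == 1]
  y <- risks[outcomes == 0]
  m <- length(x); n <- length(y)
  if (m == 0L || n == 0L) {
    stop("C statistic requires at least one case and one non-case", call. = FALSE)
  }
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' C statistic (area under the ROC curve) with DeLong confidence interval
#'
#' The C statistic is the probability that a randomly chosen case has a
#' higher risk score than a randomly chosen non-case, with ties counted one
#' half (the Mann-Whitney form). The variance is estimated from the DeLong
#' structural components and the 95% CI is normal-theory on the AUC scale,
#' truncated to \[0, 1\].
#'
#' @param cohort A [scored_cohort()].
#' @param conf Confidence level, default 0.95.
#' @return Object of class `auc_result`: list with `auc`, `variance`,
#'   `ci_low`, `ci_high`, `method` (`"delong"`), `n_cases`, `n_controls`.
#' @examples
#' coh <- scored_cohort(c(0.9, 0.8, 0.7, 0.3, 0.2), c(1, 1, 0, 1, 0))
#' c_statistic(coh)
#' @export
c_statistic <- function(cohort, conf = 0.95) {
  if (!inherits(cohort, "scored_cohort")) {
    cohort <- scored_cohort(cohort$risk, cohort$outcome)
  }
  dc <- delong_components(cohort$risk, cohort$outcome)
  v <- stats::var(dc$v10) / dc$m + stats::var(dc$v01) / dc$n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(v)
  structure(
    list(auc = dc$auc, variance = v,
         ci_low = max(0, dc$auc - half), ci_high = min(1, dc$auc + half),
         method = "delong", n_cases = dc$m, n_controls = dc$n),
    class = "auc_result"
  )
}

#' Compare two C statistics by the DeLong method
#'
#' Paired mode compares two risk scores on the *same* patients (identical
#' outcomes), using the DeLong covariance between the two sets of structural
#' components. Unpaired mode compares scores on two disjoint cohorts (for
#' example men vs. women scored by one pooled model) and assumes
#' independence, i.e. zero covariance.
#'
#' @param cohort_a,cohort_b [scored_cohort()] objects. In paired mode these
#'   must hold the same outcomes in the same order.
#' @param paired Logical; see above.
#' @return Object of class `auc_comparison`: `auc_a`, `auc_b`, `difference`
#'   (`auc_b - auc_a`), `z`, `p_value` (two-sided normal), `paired`,
#'   `method = "delong"`.
#' @export
compare_auc_delong <- function(cohort_a, cohort_b, paired = FALSE) {
  for (nm in c("cohort_a", "cohort_b")) {
    co <- get(nm)
    if (!inherits(co, "scored_cohort")) {
      assign(nm, scored_cohort(co$risk, co$outcome))
    }
  }
  da <- delong_components(cohort_a$risk, cohort_a$outcome)
  db <- delong_components(cohort_b$risk, cohort_b$outcome)
  if (paired) {
    if (nrow(cohort_a) != nrow(cohort_b) ||
        !all(cohort_a$outcome == cohort_b$outcome)) {
      stop("paired comparison requires identical outcomes on the same patients",
           call. = FALSE)
    }
    var_diff <- (stats::var(da$v10) + stats::var(db$v10) -
                   2 * stats::cov(da$v10, db$v10)) / da$m +
                (stats::var(da$v01) + stats::var(db$v01) -
                   2 * stats::cov(da$v01, db$v01)) / da$n
  } else {
    var_diff <- stats::var(da$v10) / da$m + stats::var(da$v01) / da$n +
                stats::var(db$v10) / db$m + stats::var(db$v01) / db$n
  }
  diff <- db$auc - da$auc
  if (var_diff <= 0) {
    z <- if (diff == 0) 0 else -sign(diff) * Inf
  } else {
    z <- (da$auc - db$auc) / sqrt(var_diff)
  }
  p <- 2 * stats::pnorm(-abs(z))
  structure(
    list(auc_a = da$auc, auc_b = db$auc, difference = diff,
         z = z, p_value = p, paired = paired, method = "delong"),
    class = "auc_comparison"
  )
}

#' Compare two paired C statistics by patient-level bootstrap
#'
#' Both risk vectors score the same patients. Each replicate resamples
#' patients with replacement (a resample missing either outcome class is
#' redrawn, at most 100 times) and recomputes both AUCs; the two-sided
#' p-value is the tail proportion of the bootstrap AUC-difference
#' distribution against zero, `2 * min(P(d <= 0), P(d >= 0))` capped at 1.
#'
#' @param risks_a,risks_b Risk vectors on the same patients.
#' @param outcomes Binary outcome vector.
#' @param reps Number of bootstrap replicates, at least 100 (default 2000).
#' @param seed Integer seed; required.
#' @return An `auc_comparison` with `method = "bootstrap"`, `z` absent
#'   (`NA`), plus `ci_low`/`ci_high` (percentile CI for the difference).
#' @export
compare_auc_bootstrap <- function(risks_a, risks_b, outcomes, reps = 2000, seed) {
  if (missing(seed)) stop("`seed` is required for reproducibility", call. = FALSE)
  if (length(risks_a) != length(risks_b) || length(risks_a) != length(outcomes)) {
    stop("`risks_a`, `risks_b`, `outcomes` must have equal length", call. = FALSE)
  }
  if (reps < 100) stop("`reps` must be at least 100", call. = FALSE)
  ca <- scored_cohort(risks_a, outcomes)
  cb <- scored_cohort(risks_b, outcomes)
  auc_a <- delong_components(ca$risk, ca$outcome)$auc
  auc_b <- delong_components(cb$risk, cb$outcome)$auc
  n <- length(outcomes)
  d <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      idx <- resample_with_both_classes(ca$outcome, n)
      y <- ca$outcome[idx]
      delong_components(risks_b[idx], y)$auc -
        delong_components(risks_a[idx], y)$auc
    }, numeric(1))
  })
  p <- min(1, 2 * min(mean(d <= 0), mean(d >= 0)))
  structure(
    list(auc_a = auc_a, auc_b = auc_b, difference = auc_b - auc_a,
         z = NA_real_, p_value = p, paired = TRUE, method = "bootstrap",
         ci_low = unname(stats::quantile(d, 0.025)),
         ci_high = unname(stats::quantile(d, 0.975)),
         reps = reps, seed = seed),
    class = "auc_comparison"
  )
}

#' ROC curve of a scored cohort
#'
#' Operating points (false-positive rate, sensitivity) over all distinct
#' risk thresholds in descending order, anchored at (0, 0) and (1, 1). Built
#' from the same threshold sweep as the CU curve: at every threshold,
#' 1 - specificity here equals FP / (total non-cases) there.
#'
#' @param cohort A [scored_cohort()].
#' @return Object of class `roc_curve`: data frame with columns `threshold`
#'   (`Inf` for the (0,0) anchor), `fpr`, `sensitivity`.
#' @export
roc_curve <- function(cohort) {
  if (!inherits(cohort, "scored_cohort")) {
    cohort <- scored_cohort(cohort$risk, cohort$outcome)
  }
  check_two_classes(cohort)
  risk <- cohort$risk; outcome <- cohort$outcome
  n <- length(risk)
  n_cases <- sum(outcome == 1); n_controls <- n - n_cases
  ord <- order(risk, decreasing = TRUE)
  y_sorted <- outcome[ord]; r_sorted <- risk[ord]
  is_block_end <- c(r_sorted[-n] != r_sorted[-1], TRUE)
  tp <- cumsum(y_sorted)[is_block_end]
  flagged <- seq_len(n)[is_block_end]
  pts <- data.frame(
    threshold = c(Inf, r_sorted[is_block_end]),
    fpr = c(0, (flagged - tp) / n_controls),
    sensitivity = c(0, tp / n_cases)
  )
  class(pts) <- c("roc_curve", "data.frame")
  pts
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("C statistic %.3f (95%% CI %.3f-%.3f), %s method; %d cases / %d non-cases\n",
              x$auc, x$ci_low, x$ci_high, x$method, x$n_cases, x$n_controls))
  invisible(x)
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("C statistics %.3f vs %.3f (difference %+.3f), %s%s method: P = %.3g\n",
              x$auc_a, x$auc_b, x$difference,
              if (x$paired) "paired " else "unpaired ", x$method, x$p_value))
  invisible(x)
}
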