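test_that("C statistic handles the degenerate extremes", {
  perfect <- scored_cohort(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(c_statistic(perfect)$auc, 1)
  tied <- scored_cohort(rep(0.4, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(c_statistic(tied)$auc, 0.5)
  expect_error(c_statistic(scored_cohort(c(0.1, 0.2), c(1, 1))),
               "at least one case and one non-case")
})

test_that("C statistic equals exhaustive pair counting on random tied cohorts", {
  for (seed in 1:10) {
    coh <- random_tied_cohort(15, seed = 300 + seed)
    expect_identical(c_statistic(coh)$auc, oracle_auc(coh$risk, coh$outcome))
  }
})

test_that("AUC and DeLong variance agree with pROC as an independent reference", {
  skip_if_not_installed("pROC")
  coh <- generate_binormal_cohort(35, 45, mean_case = 0.9, seed = 17)
  got <- c_statistic(coh)
  ref <- pROC::roc(coh$outcome, coh$risk, quiet = TRUE, direction = "<")
  expect_equal(got$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(got$variance, as.numeric(pROC::var(ref, method = "delong")),
               tolerance = 1e-10)
  # paired DeLong test against pROC on two correlated scores
  risks_b <- plogis(qlogis(coh$risk) + withr::with_seed(5, rnorm(80, 0, 0.8)))
  cmp <- compare_auc_delong(coh, scored_cohort(risks_b, coh$outcome), paired = TRUE)
  ref2 <- pROC::roc.test(ref, pROC::roc(coh$outcome, risks_b, quiet = TRUE,
                                        direction = "<"), method = "delong")
  expect_equal(cmp$p_value, as.numeric(ref2$p.value), tolerance = 1e-10)
})

test_that("AUC is invariant to monotone transforms and symmetric under label swap", {
  coh <- random_tied_cohort(60, seed = 41)
  a <- c_statistic(coh)$auc
  expect_equal(c_statistic(scored_cohort(coh$risk^2, coh$outcome))$auc, a)
  flipped <- scored_cohort(1 - coh$risk, coh$outcome)
  expect_equal(c_statistic(flipped)$auc, 1 - a)
})

test_that("comparing a model with itself is an exact null", {
  coh <- generate_binormal_cohort(30, 30, seed = 2)
  self <- compare_auc_delong(coh, coh, paired = TRUE)
  expect_equal(self$difference, 0)
  expect_equal(self$p_value, 1)
  bs <- compare_auc_bootstrap(coh$risk, coh$risk, coh$outcome, reps = 200, seed = 3)
  expect_equal(bs$difference, 0)
  expect_equal(bs$p_value, 1)
})

test_that("paired comparison enforces identical outcomes", {
  a <- scored_cohort(c(0.8, 0.6, 0.2), c(1, 0, 0))
  b <- scored_cohort(c(0.7, 0.5, 0.4), c(1, 1, 0))
  expect_error(compare_auc_delong(a, b, paired = TRUE), "identical outcomes")
})

test_that("bootstrap and paired DeLong p-values agree on a clear AUC gap", {
  # two correlated scores with a genuine difference in discrimination
  n <- 500
  dat <- withr::with_seed(101, {
    y <- rbinom(n, 1, 0.4)
    strong <- rnorm(n, mean = 1.5 * y)
    weak <- strong + rnorm(n, sd = 2.0)
    list(y = y, a = plogis(weak), b = plogis(strong))
  })
  dl <- compare_auc_delong(scored_cohort(dat$a, dat$y),
                           scored_cohort(dat$b, dat$y), paired = TRUE)
  bs <- compare_auc_bootstrap(dat$a, dat$b, dat$y, reps = 2000, seed = 7)
  expect_equal(bs$p_value, dl$p_value, tolerance = 0.02)
  expect_gt(bs$difference, 0)
})

test_that("DeLong variance tracks the empirical sampling variance of the AUC", {
  res <- vapply(1:500, function(s) {
    cs <- c_statistic(generate_binormal_cohort(1000, 1000, mean_case = 1,
                                               seed = 500 + s))
    c(cs$auc, cs$variance)
  }, numeric(2))
  # mean DeLong estimate vs the empirical sampling variance, 15% relative
  expect_equal(mean(res[2, ]), var(res[1, ]), tolerance = 0.15)
})

test_that("ROC curve is anchored, monotone, and threshold-consistent with the CU sweep", {
  for (seed in 1:5) {
    coh <- random_tied_cohort(40, seed = 600 + seed)
    roc <- roc_curve(coh)
    expect_equal(unlist(roc[1, c("fpr", "sensitivity")], use.names = FALSE), c(0, 0))
    expect_equal(unlist(roc[nrow(roc), c("fpr", "sensitivity")],
                        use.names = FALSE), c(1, 1))
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$sensitivity) >= 0))
    # same operating points as the CU machinery, threshold by threshold
    cu <- build_cu_curve(coh)$points
    roc_sub <- roc[match(cu$threshold, roc$threshold), ]
    expect_equal(roc_sub$fpr, 1 - cu$specificity, tolerance = 1e-12)
    expect_equal(roc_sub$sensitivity, cu$sensitivity, tolerance = 1e-12)
  }
})
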