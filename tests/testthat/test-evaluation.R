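test_that("AUC handles perfect, uninformative and degenerate inputs", {
  expect_equal(roc_auc(c(5, 6, 7, 1, 2, 3), c(1, 1, 1, 0, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(4, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "negative")
  expect_error(roc_auc(1:5, rep(FALSE, 5)), "positive")
  expect_error(roc_auc(c(1, NA), c(TRUE, FALSE)), "missing")
})

test_that("trapezoidal AUC equals the O(n^2) Mann-Whitney oracle", {
  for (s in 1:12) {
    set.seed(s)
    n <- 200
    scores <- sample(0:15, n, replace = TRUE)
    labels <- runif(n) < plogis(scores / 4 - 2)
    if (sum(labels) == 0 || sum(labels) == n) next
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-10)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(41)
  scores <- sample(0:20, 300, replace = TRUE)
  labels <- runif(300) < plogis(scores / 5 - 2)
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(scores^3 + 2, labels), a, tolerance = 1e-12)
  expect_equal(roc_auc(exp(scores / 10), labels), a, tolerance = 1e-12)
})

test_that("ROC points are a monotone curve from (0,0) to (1,1)", {
  set.seed(42)
  scores <- sample(0:12, 500, replace = TRUE)
  labels <- runif(500) < plogis(scores / 3 - 2)
  pts <- roc_curve(scores, labels)
  expect_false(is.unsorted(pts$fpr))
  expect_false(is.unsorted(pts$tpr))
  expect_equal(c(pts$fpr[1], pts$tpr[1]), c(0, 0))
  expect_equal(c(pts$fpr[nrow(pts)], pts$tpr[nrow(pts)]), c(1, 1))
})

test_that("average precision equals the brute-force oracle", {
  expect_equal(pr_auc(c(5, 6, 7, 1, 2, 3), c(1, 1, 1, 0, 0, 0)), 1.0)
  # uninformative constant score -> prevalence
  expect_equal(pr_auc(rep(3, 20), c(rep(TRUE, 4), rep(FALSE, 16))), 0.2)
  for (s in 1:8) {
    set.seed(100 + s)
    scores <- sample(0:15, 200, replace = TRUE)
    labels <- runif(200) < plogis(scores / 4 - 2)
    if (sum(labels) == 0) next
    expect_equal(pr_auc(scores, labels),
                 oracle_average_precision(scores, labels), tolerance = 1e-12)
  }
})

test_that("DeLong interval brackets the point estimate and narrows with n", {
  gen <- function(n, seed) {
    set.seed(seed)
    scores <- sample(0:15, n, replace = TRUE)
    labels <- runif(n) < plogis(scores / 4 - 1.5)
    list(s = scores, l = labels)
  }
  small <- gen(100, 51); big <- gen(1000, 51)
  ci_s <- delong_auc_ci(small$s, small$l)
  ci_b <- delong_auc_ci(big$s, big$l)
  expect_true(ci_s$ci[1] <= ci_s$auc && ci_s$auc <= ci_s$ci[2])
  expect_true(ci_b$ci[1] <= ci_b$auc && ci_b$auc <= ci_b$ci[2])
  expect_lt(diff(ci_b$ci), diff(ci_s$ci))
  # DeLong AUC equals the trapezoidal/mid-rank AUC
  expect_equal(ci_b$auc, roc_auc(big$s, big$l), tolerance = 1e-12)
})

test_that("stratified bootstrap is seeded and reproducible bit-exact", {
  set.seed(52)
  scores <- sample(0:15, 400, replace = TRUE)
  labels <- runif(400) < plogis(scores / 4 - 1.5)
  b1 <- bootstrap_metric_ci(scores, labels, pr_auc, n_boot = 300, seed = 7)
  b2 <- bootstrap_metric_ci(scores, labels, pr_auc, n_boot = 300, seed = 7)
  expect_identical(b1, b2)
  b3 <- bootstrap_metric_ci(scores, labels, pr_auc, n_boot = 300, seed = 8)
  expect_false(identical(b1$ci, b3$ci))
  expect_true(b1$ci[1] <= b1$estimate && b1$estimate <= b1$ci[2])
})

test_that("evaluate_scores bundles consistent ROC and PR results", {
  set.seed(53)
  scores <- sample(0:15, 600, replace = TRUE)
  labels <- runif(600) < plogis(scores / 4 - 2)
  ev <- evaluate_scores(scores, labels, n_boot = 200, seed = 3)
  expect_equal(ev$auc, oracle_auc(scores, labels), tolerance = 1e-10)
  expect_equal(ev$auc_pr, oracle_average_precision(scores, labels),
               tolerance = 1e-12)
  expect_equal(ev$n_pos + ev$n_neg, 600)
  expect_true(ev$auc_ci[1] <= ev$auc && ev$auc <= ev$auc_ci[2])
  expect_true(ev$auc_pr_ci[1] <= ev$auc_pr + 1e-12 &&
                ev$auc_pr <= ev$auc_pr_ci[2] + 1e-12)
  # bootstrap AUC interval cross-checks DeLong (generous overlap check)
  expect_gt(min(ev$auc_ci_boot[2], ev$auc_ci[2]),
            max(ev$auc_ci_boot[1], ev$auc_ci[1]))
})

test_that("substitution analysis: identity, formula, and identical-table cases", {
  co <- generate_cohort(cohort_config(n_admissions = 1200, seed = 54))
  pp <- preprocess_observations(co$observations)
  lab <- label_observations(pp$observations, co$events, 24)
  obs <- lab$labeled; labels <- lab$labeled$label

  base <- cews_continuous()
  self <- substitution_analysis(base, base, obs, labels)
  expect_true(all(self$by_variable$pct_change == 0))

  rep <- substitution_analysis(base, cews_manual(oxygen = FALSE), obs, labels)
  # percentage-change formula is recomputable from the stored AUCs
  expect_equal(rep$by_variable$pct_change,
               (rep$by_variable$auc - rep$base_auc) / rep$base_auc * 100,
               tolerance = 1e-12)
  # SpO2 band tables are identical in the two systems -> exactly 0
  expect_equal(rep$by_variable$pct_change[rep$by_variable$variable == "spo2"], 0)

  bad <- cews_manual(oxygen = FALSE); bad$tables$spo2 <- NULL
  expect_error(substitution_analysis(base, bad, obs, labels),
               "same variables")
})
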