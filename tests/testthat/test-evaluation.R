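test_that("AUC equals exhaustive pair counting with half-weight ties", {
  expect_equal(auc(c(2, 3), c(0, 1)), 1)
  expect_equal(auc(c(0.9, 0.8), c(0.85, 0.1)), 0.75)  # 3 wins of 4 pairs
  expect_equal(auc(rep(1, 5), rep(1, 7)), 0.5)
  set.seed(3)
  for (rep in 1:8) {
    cases <- sample(0:5, 9, replace = TRUE)   # ties on purpose
    controls <- sample(0:5, 7, replace = TRUE)
    pairs <- outer(cases, controls, function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(auc(cases, controls), mean(pairs))
    # complement property (general, including ties)
    expect_equal(auc(cases, controls) + auc(controls, cases), 1)
  }
})

test_that("ROC points are monotone and their trapezoidal area is the AUC", {
  set.seed(5)
  cases <- rnorm(15, 1); controls <- rnorm(20)
  r <- roc_points(cases, controls)
  expect_true(!is.unsorted(r$fpr) && !is.unsorted(r$tpr))
  expect_equal(r$fpr[nrow(r)], 1)
  area <- sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
  expect_equal(area, auc(cases, controls), tolerance = 1e-12)
})

test_that("DeLong machinery: self-comparison, degenerate limit, CI bracket", {
  set.seed(7)
  sc <- rnorm(40); lab <- rep(c(TRUE, FALSE), 20)
  self <- delong_ci_and_test(sc, sc, lab)
  expect_equal(self$delta, 0)
  expect_equal(self$p_difference, 1)
  # perfect separation at large n: variance collapses, CI pinches to [1,1]
  big <- delong_ci(rnorm(400) + 100, rnorm(400))
  expect_equal(big$auc, 1)
  expect_equal(big$ci, c(1, 1))
  cases <- rnorm(30, 1); controls <- rnorm(30)
  d <- delong_ci(cases, controls)
  expect_true(d$ci[1] <= d$auc && d$auc <= d$ci[2])
  # the DeLong point estimate is the pair-counting AUC, exactly
  expect_equal(d$auc, auc(cases, controls))
})

test_that("DeLong paired p-value agrees with a bootstrap oracle", {
  set.seed(19)
  n <- 30
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  latent <- rnorm(n) + 1.2 * lab
  a <- latent + rnorm(n, sd = 0.7)
  b <- 0.4 * latent + rnorm(n, sd = 1)
  res <- delong_ci_and_test(a, b, lab)
  B <- 4000
  deltas <- vapply(seq_len(B), function(i) {
    idx <- c(sample(which(lab), sum(lab), replace = TRUE),
             sample(which(!lab), sum(!lab), replace = TRUE))
    auc(a[idx][lab[idx]], a[idx][!lab[idx]]) -
      auc(b[idx][lab[idx]], b[idx][!lab[idx]])
  }, numeric(1))
  p_boot <- 2 * pnorm(-abs(res$delta) / sd(deltas))
  expect_lt(abs(res$p_difference - p_boot), 0.02)
  expect_error(delong_ci_and_test(a, b[-1], lab), "equal-length")
})

test_that("specificity percentages reproduce the published count arithmetic", {
  expect_equal(specificity_percent(161, 170), 94.7)
  expect_equal(specificity_percent(109, 110), 99.1)
  expect_equal(specificity_percent(10, 10), 100)
  set.seed(1)
  for (rep in 1:20) {
    t <- sample(1:500, 1); c <- sample(0:t, 1)
    expect_equal(specificity_percent(c, t), round(100 * c / t, 1))
  }
})

test_that("independent specificity counts below-cutoff scores and rejects cases", {
  d <- separable_dataset()
  fit <- fit_svm(d, colnames(d$intensities))
  cv <- loo_cv_scores(d, colnames(d$intensities))
  fit <- set_panel_cutoff(fit, cv)
  controls <- subset_dataset(d, samples = d$group == "sFSGS")
  res <- independent_specificity(fit, controls)
  expect_equal(res$n_total, sum(d$group == "sFSGS"))
  expect_equal(res$specificity,
               specificity_percent(res$n_correct, res$n_total))
  expect_equal(res$specificity, 100)  # separable: all controls below cutoff
  expect_error(independent_specificity(fit, d), "without pFSGS")
})

test_that("covariable screen recovers known coefficients and flags null terms", {
  set.seed(23)
  hits <- 0L
  for (s in 1:10) {
    n <- 500
    score <- rnorm(n)
    covs <- data.frame(proteinuria = rlnorm(n), eGFR = rnorm(n, 60, 20),
                       age = rnorm(n, 50, 15),
                       sex = sample(c("M", "F"), n, TRUE),
                       IFTA = runif(n, 0, 60))
    y <- rbinom(n, 1, plogis(-1 + 1.5 * score))
    m <- matrix(rlnorm(n), n, 1, dimnames = list(paste0("s", 1:n), "pep1"))
    d <- intensity_dataset(m, ifelse(y == 1, "pFSGS", "sFSGS"),
                           covariates = covs)
    fit <- covariable_screen(d, score)
    est <- fit$estimate[fit$term == "score"]
    se <- fit$se[fit$term == "score"]
    hits <- hits + (abs(est - 1.5) <= 2 * se)
    # null covariates stay near zero
    expect_lt(abs(fit$estimate[fit$term == "age"]), 0.1)
  }
  expect_gte(hits, 8L)
})

test_that("covariable screen flags separation and applies the labelled fallback", {
  set.seed(2)
  n <- 60
  score <- c(rnorm(30, 5), rnorm(30, -5))   # perfectly separating
  covs <- data.frame(proteinuria = rlnorm(n), eGFR = rnorm(n, 60, 20),
                     age = rnorm(n, 50, 15),
                     sex = sample(c("M", "F"), n, TRUE),
                     IFTA = runif(n, 0, 60))
  m <- matrix(rlnorm(n), n, 1, dimnames = list(paste0("s", 1:n), "pep1"))
  d <- intensity_dataset(m, rep(c("pFSGS", "sFSGS"), each = 30),
                         covariates = covs)
  fit <- covariable_screen(d, score)
  expect_true(attr(fit, "penalized"))
  expect_equal(nrow(fit), 7L)  # intercept + 6 terms
})

test_that("nomogram combines predictors sensibly", {
  set.seed(13)
  n <- 400
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  # two independent, individually informative predictors
  score <- rnorm(n) + 0.9 * lab
  prot <- rlnorm(n, 0.9 * lab, 1)
  nm <- build_nomogram(score, prot, lab)
  expect_gt(nm$auc_combined, nm$auc_score)
  expect_gt(nm$auc_combined, nm$auc_proteinuria)
  expect_true(nm$vs_proteinuria$p_difference >= 0 &&
                nm$vs_proteinuria$p_difference <= 1)
  # in-sample logistic combination never much below the best single term
  expect_gte(nm$auc_combined,
             max(nm$auc_score, nm$auc_proteinuria) - 0.02)
  # uninformative second term: combination ~ classifier alone
  prot_null <- rlnorm(n)
  nm0 <- build_nomogram(score, prot_null, lab)
  expect_lt(abs(nm0$auc_combined - nm0$auc_score), 0.05)
  expect_error(build_nomogram(score, rep(1, n), lab), "constant")
})

test_that("cohort-table tests dispatch correctly and match the printed p-value", {
  counts <- matrix(c(14, 5, 14, 30), 2, byrow = TRUE)
  expect_equal(round(cohort_table_stats(counts, kind = "categorical"), 4),
               0.0052)
  even <- matrix(c(10, 10, 10, 10), 2)
  expect_equal(cohort_table_stats(even, kind = "categorical"), 1)
  set.seed(4)
  x <- rnorm(25, 50, 8); y <- rnorm(30, 54, 8)
  expect_equal(cohort_table_stats(x, y, kind = "normal"),
               t.test(x, y, var.equal = TRUE)$p.value)
  expect_equal(cohort_table_stats(x, y, kind = "skewed"),
               wilcoxon_rank_sum(x, y))
  expect_error(cohort_table_stats(x, kind = "normal"), "two raw value")
  expect_error(cohort_table_stats(counts, y, kind = "categorical"),
               "single 2x2")
})

test_that("Yates chi-square tracks an exact enumeration oracle where it matters", {
  # the continuity correction is an approximation to the exact conditional
  # test; agreement is tight in the decision-relevant small-p regime, and
  # the two tests agree on significance calls almost always
  set.seed(8)
  agree <- 0L; n_small <- 0L
  for (rep in 1:60) {
    n1 <- sample(40:80, 1); n2 <- sample(40:80, 1)
    a <- sample(8:(n1 - 8), 1); b <- sample(8:(n2 - 8), 1)
    tab <- matrix(c(a, n1 - a, b, n2 - b), 2, byrow = TRUE)
    p_yates <- suppressWarnings(cohort_table_stats(tab, kind = "categorical"))
    p_exact <- fisher.test(tab)$p.value
    agree <- agree + ((p_yates < 0.05) == (p_exact < 0.05))
    if (p_exact < 0.05) {
      n_small <- n_small + 1L
      expect_lt(abs(p_yates - p_exact), 0.02)
    }
  }
  expect_gte(agree / 60, 0.9)
  expect_gte(n_small, 5L)  # the small-p regime was actually exercised
})
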