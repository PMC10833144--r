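test_that("the two-point problem yields the perpendicular bisector", {
  # hard-margin limit: w = 2 d / ||d||^2, boundary through the midpoint
  Z <- rbind(c(1, 1), c(-1, -1))
  fit <- urinepanel:::svm_solve(Z, c(1, -1), C = 100)
  expect_equal(fit$w, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(fit$b, 0, tolerance = 1e-6)
  expect_equal(drop(Z %*% fit$w) + fit$b, c(1, -1), tolerance = 1e-6)
  # off-center pair: margin midpoint, not the origin
  Z2 <- rbind(c(3, 0), c(1, 0))
  fit2 <- urinepanel:::svm_solve(Z2, c(1, -1), C = 100)
  expect_equal(drop(Z2 %*% fit2$w) + fit2$b, c(1, -1), tolerance = 1e-6)
})

test_that("separable data are scored in the right order", {
  d <- separable_dataset()
  fit <- fit_svm(d, colnames(d$intensities))
  sc <- score_samples(fit, d)
  expect_gt(min(sc$score[d$group == "pFSGS"]),
            max(sc$score[d$group == "sFSGS"]))
})

test_that("the decision function is invariant to sample and feature order", {
  d <- separable_dataset(delta = 1)
  fit <- fit_svm(d, colnames(d$intensities))
  set.seed(8)
  perm <- sample(nrow(d$intensities))
  fit_p <- fit_svm(subset_dataset(d, samples = perm),
                   colnames(d$intensities))
  expect_equal(fit_p$w, fit$w, tolerance = 1e-8)
  expect_equal(fit_p$b, fit$b, tolerance = 1e-8)
  # permuting peptide columns of the scoring data changes nothing
  d_shuf <- subset_dataset(d, peptides = rev(colnames(d$intensities)))
  expect_equal(score_samples(fit, d_shuf)$score,
               score_samples(fit, d)$score, tolerance = 1e-12)
})

test_that("degenerate training inputs are rejected", {
  d <- separable_dataset()
  expect_error(fit_svm(d, character(0)), "empty feature")
  expect_error(fit_svm(d, "nope"), "absent")
  single <- subset_dataset(d, samples = d$group == "pFSGS")
  expect_error(fit_svm(single, colnames(d$intensities)), "single class")
})

test_that("held-out LOO scores separate separable data and not permuted labels", {
  d <- separable_dataset(n_case = 6, n_control = 7)
  cv <- loo_cv_scores(d, colnames(d$intensities))
  expect_equal(auc(cv$score[cv$is_case], cv$score[!cv$is_case]), 1)
  # label permutation null: CV AUC hovers around 0.5
  set.seed(15)
  m <- d$intensities
  aucs <- replicate(12, {
    dp <- intensity_dataset(m, sample(as.character(d$group)))
    cvp <- loo_cv_scores(dp, colnames(m))
    auc(cvp$score[cvp$is_case], cvp$score[!cvp$is_case])
  })
  expect_gt(mean(aucs), 0.25)
  expect_lt(mean(aucs), 0.75)
})

test_that("each fold is fitted without its held-out sample (no leakage)", {
  d <- informative_dataset(8, 8, k_info = 3, seed = 3)
  cv <- loo_cv_scores(d, colnames(d$intensities))
  # fold accounting: the fold model for sample 1 is exactly the fit on 2..n
  fold1 <- fit_svm(subset_dataset(d, samples = -1), colnames(d$intensities))
  expect_equal(score_samples(fold1, subset_dataset(d, samples = 1))$score,
               cv$score[1], tolerance = 1e-12)
  # inject an extreme held-out sample: its fold's transform constants and
  # hyperplane are untouched, so its held-out score uses no self-information
  m2 <- d$intensities
  m2[1, ] <- m2[1, ] * 1e6
  d2 <- intensity_dataset(m2, as.character(d$group))
  fold1_extreme <- fit_svm(subset_dataset(d2, samples = -1),
                           colnames(d$intensities))
  expect_identical(fold1_extreme$center, fold1$center)
  expect_identical(fold1_extreme$scale, fold1$scale)
  expect_equal(fold1_extreme$w, fold1$w, tolerance = 1e-12)
  cv2 <- loo_cv_scores(d2, colnames(d$intensities))
  expect_equal(cv2$score[1],
               score_samples(fold1, subset_dataset(d2, samples = 1))$score,
               tolerance = 1e-12)
})

test_that("backward elimination drops a pure-noise feature and stops honestly", {
  removed <- logical(6)
  for (s in 1:6) {
    d <- block_panel_dataset(seed = 400 + s)
    out <- take_one_out_elimination(d, colnames(d$intensities))
    removed[s] <- !"noise1" %in% out$features
    expect_true(all(paste0("info", 1:3) %in% out$features))
    # never removes a feature whose removal reduces the AUC beyond tol,
    # so the trace never dips and the final panel is at least as good as
    # the full one
    expect_true(all(diff(out$trace$auc_after) >= -1e-6))
    expect_gte(out$trace$auc_after[nrow(out$trace)],
               out$trace$auc_after[1] - 1e-6)
    expect_gte(length(out$features), 1L)
  }
  expect_gte(sum(removed), 5)
  # strict mode stops as soon as nothing improves: removes nothing when the
  # panel is already at its ceiling
  d <- separable_dataset(n_case = 6, n_control = 6)
  out <- take_one_out_elimination(d, colnames(d$intensities), mode = "strict")
  expect_equal(nrow(out$trace), 1L)
  expect_setequal(out$features, colnames(d$intensities))
})

test_that("elimination leaves a single feature untouched", {
  d <- informative_dataset(6, 6, k_info = 1, seed = 2)
  out <- take_one_out_elimination(d, "info1")
  expect_equal(out$features, "info1")
  expect_equal(nrow(out$trace), 0L)
})

test_that("Youden cutoff matches exhaustive search and the known cases", {
  yc <- youden_cutoff(c(1, 2), c(-1, 0))
  expect_equal(yc$cutoff, 0.5)
  expect_equal(yc$j, 1)
  expect_equal(yc$sensitivity_pct, 100)
  expect_equal(yc$specificity_pct, 100)
  set.seed(10)
  for (rep in 1:10) {
    cases <- rnorm(9, 1); controls <- rnorm(11)
    yc <- youden_cutoff(cases, controls)
    expect_equal(yc$j, youden_oracle(cases, controls), tolerance = 1e-12)
    # ties in J resolve toward higher specificity
    expect_equal(yc$specificity, mean(controls < yc$cutoff))
  }
  expect_error(youden_cutoff(numeric(0), 1), "both classes")
})

test_that("scoring is deterministic, constant on zero input, robust to absent peptides", {
  d <- separable_dataset()
  fit <- fit_svm(d, colnames(d$intensities))
  s1 <- score_samples(fit, d)$score
  expect_identical(s1, score_samples(fit, d)$score)
  zero <- intensity_dataset(
    matrix(0, 4, 3, dimnames = list(paste0("z", 1:4),
                                    colnames(d$intensities))),
    rep("NC", 4))
  sz <- score_samples(fit, zero)$score
  expect_equal(max(sz) - min(sz), 0)
  partial <- subset_dataset(d, peptides = 1:2)
  expect_warning(sp <- score_samples(fit, partial), "absent")
  expect_equal(length(sp$score), nrow(d$intensities))
})

test_that("panel JSON round-trips to identical scores and metadata", {
  d <- separable_dataset()
  fit <- fit_svm(d, colnames(d$intensities))
  cv <- loo_cv_scores(d, colnames(d$intensities))
  fit <- set_panel_cutoff(fit, cv)
  path <- withr::local_tempfile(fileext = ".json")
  write_panel(fit, path)
  back <- read_panel(path)
  expect_equal(score_samples(back, d), score_samples(fit, d))
  expect_equal(back$cutoff, fit$cutoff)
  expect_equal(back$meta$cv$auc, fit$meta$cv$auc)
})
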