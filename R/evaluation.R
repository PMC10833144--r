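#' Area under the ROC curve
#'
#' Tie-corrected pair-win fraction: the probability that a randomly chosen
#' case outscores a randomly chosen control, with ties counted one half.
#' Identical to the trapezoidal area under the empirical ROC curve.
#'
#' @param cases,controls numeric score vectors, both non-empty.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(cases, controls) {
  n1 <- length(cases); n0 <- length(controls)
  if (n1 == 0 || n0 == 0) stop("both classes must be non-empty")
  r <- rank(c(cases, controls))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve points
#'
#' @param cases,controls numeric score vectors.
#' @return data.frame of `(fpr, tpr)` points from (0, 0) to (1, 1), one per
#'   distinct threshold, monotone non-decreasing in both coordinates.
#' @export
roc_points <- function(cases, controls) {
  thr <- sort(unique(c(cases, controls)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(cases >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(controls >= t), numeric(1))
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

## DeLong placement values: psi(case_i, control_j) averaged over the other
## class, for cases (V10) and controls (V01).
delong_placements <- function(cases, controls) {
  n1 <- length(cases); n0 <- length(controls)
  r <- rank(c(cases, controls))
  rc <- rank(cases); rn <- rank(controls)
  v10 <- (r[seq_len(n1)] - rc) / n0
  v01 <- 1 - (r[n1 + seq_len(n0)] - rn) / n1
  list(v10 = v10, v01 = v01,
       auc = (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0))
}

#' AUC with DeLong 95% confidence interval
#'
#' Nonparametric (DeLong) variance of the AUC estimator; the normal
#' approximation CI is truncated to `[0, 1]`.
#'
#' @param cases,controls numeric score vectors.
#' @param conf confidence level.
#' @return list with `auc`, `se`, `ci` (length-2), `n_cases`, `n_controls`.
#' @export
delong_ci <- function(cases, controls, conf = 0.95) {
  pl <- delong_placements(cases, controls)
  s10 <- stats::var(pl$v10); s01 <- stats::var(pl$v01)
  se <- sqrt(s10 / length(cases) + s01 / length(controls))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(auc = pl$auc, se = se,
       ci = pmin(1, pmax(0, pl$auc + c(-1, 1) * z * se)),
       n_cases = length(cases), n_controls = length(controls))
}

#' DeLong paired comparison of two ROC curves
#'
#' Both scores must be measured on the same samples. Returns each AUC with
#' its DeLong CI and the two-sided p-value of the paired AUC difference
#' (normal approximation with the DeLong covariance).
#'
#' @param scores_a,scores_b numeric score vectors over the same samples.
#' @param is_case logical vector: `TRUE` for cases.
#' @param conf confidence level for the per-score CIs.
#' @return list with `auc_a`, `auc_b`, `ci_a`, `ci_b`, `delta`, `se_delta`,
#'   `p_difference`.
#' @export
delong_ci_and_test <- function(scores_a, scores_b, is_case, conf = 0.95) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(is_case))
    stop("paired comparison requires equal-length score and label vectors")
  is_case <- as.logical(is_case)
  pa <- delong_placements(scores_a[is_case], scores_a[!is_case])
  pb <- delong_placements(scores_b[is_case], scores_b[!is_case])
  n1 <- sum(is_case); n0 <- sum(!is_case)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / n1 + s01 / n0
  delta <- pa$auc - pb$auc
  se <- sqrt(max(0, S[1, 1] + S[2, 2] - 2 * S[1, 2]))
  p <- if (se == 0) 1 else 2 * stats::pnorm(-abs(delta) / se)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(auc_a = pa$auc, auc_b = pb$auc,
       ci_a = pmin(1, pmax(0, pa$auc + c(-1, 1) * z * sqrt(S[1, 1]))),
       ci_b = pmin(1, pmax(0, pb$auc + c(-1, 1) * z * sqrt(S[2, 2]))),
       delta = delta, se_delta = se, p_difference = p)
}

#' Percent specificity from counts
#'
#' @param n_correct,n_total nonnegative counts, `n_correct <= n_total`.
#' @return percent, rounded to one decimal.
#' @export
specificity_percent <- function(n_correct, n_total) {
  stopifnot(n_total > 0, n_correct >= 0, n_correct <= n_total)
  round(100 * n_correct / n_total, 1)
}

#' Independent specificity of a trained panel
#'
#' Scores a dataset of non-case samples (normal controls or other-CKD
#' patients) and counts those correctly classified as "not pFSGS", i.e.
#' scoring below the stored cutoff.
#'
#' @param panel a `trained_panel` with a cutoff set.
#' @param data an [intensity_dataset()] containing no pFSGS samples.
#' @return list with `n_correct`, `n_total` and `specificity` (percent,
#'   one decimal).
#' @export
independent_specificity <- function(panel, data) {
  stopifnot(inherits(panel, "trained_panel"),
            inherits(data, "intensity_dataset"))
  if (is.null(panel$cutoff)) stop("panel has no cutoff set")
  if (any(data$group == "pFSGS"))
    stop("specificity evaluation requires a dataset without pFSGS samples")
  sc <- score_samples(panel, data)
  n_correct <- sum(sc$score < panel$cutoff)
  list(n_correct = as.integer(n_correct), n_total = nrow(sc),
       specificity = specificity_percent(n_correct, nrow(sc)))
}

#' Multivariable covariable screen
#'
#' Logistic regression of case status on the classifier score and the
#' clinical covariables (sex, age, proteinuria, eGFR, IFTA by default),
#' fitted on complete cases, with per-term Wald p-values. If the fit shows
#' (quasi-)complete separation, a weakly ridge-penalized refit is used and
#' labelled as such.
#'
#' @param data an [intensity_dataset()] with covariates.
#' @param scores numeric classifier score per sample (same order as the
#'   dataset's samples).
#' @param terms covariable names to include alongside the score.
#' @param case_group the positive outcome label.
#' @return object of class `covariable_model`: data.frame of terms with
#'   `estimate`, `se`, `z`, `p`; attributes `n`, `n_events`, `penalized`.
#' @export
covariable_screen <- function(data, scores,
                              terms = c("sex", "age", "proteinuria",
                                        "eGFR", "IFTA"),
                              case_group = "pFSGS") {
  stopifnot(inherits(data, "intensity_dataset"))
  if (is.null(data$covariates)) stop("dataset carries no covariates")
  df <- data$covariates[, intersect(terms, names(data$covariates)),
                        drop = FALSE]
  df$score <- scores
  df$y <- as.integer(data$group == case_group)
  if ("sex" %in% names(df)) df$sex <- as.integer(df$sex == "M")
  df <- df[stats::complete.cases(df), ]
  if (sum(df$y) < 10)
    stop("fewer than 10 events among complete cases")
  X <- as.matrix(df[, setdiff(names(df), "y"), drop = FALSE])
  # separation is detected and handled below; glm's own warnings are noise
  fit <- suppressWarnings(stats::glm(df$y ~ X, family = stats::binomial()))
  penalized <- FALSE
  co <- summary(fit)$coefficients
  if (!fit$converged || any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE) ||
      anyNA(stats::coef(fit))) {
    # separation fallback: small-L2 ridge logistic via penalized IRLS
    fitr <- ridge_logistic(cbind(1, X), df$y, lambda = 1e-2)
    co <- fitr
    penalized <- TRUE
  }
  out <- data.frame(term = c("(Intercept)", colnames(X)),
                    estimate = co[, 1], se = co[, 2],
                    z = co[, 1] / co[, 2],
                    p = 2 * stats::pnorm(-abs(co[, 1] / co[, 2])),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("covariable_model", "data.frame"),
            n = nrow(df), n_events = sum(df$y), penalized = penalized)
}

## L2-penalized logistic regression by IRLS (intercept unpenalized).
## Used only as the labelled fallback under separation.
ridge_logistic <- function(X, y, lambda, maxit = 200, tol = 1e-10) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(c(0, rep(lambda, p - 1)))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    Wv <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * Wv) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(H)))
  cbind(estimate = beta, se = se)
}

#' Two-term nomogram: classifier score plus proteinuria
#'
#' Combines the panel score and proteinuria in a logistic model, the
#' standard reduction of a graphical nomogram to its defining coefficients.
#' Returns the combined linear predictor per sample, a 0-100 points scale
#' per term (points proportional to coefficient times observed range), the
#' combined AUC, and DeLong comparisons of the combination against each
#' single predictor.
#'
#' @param scores numeric classifier scores.
#' @param proteinuria numeric proteinuria values (g/d), same samples.
#' @param is_case logical outcome.
#' @return object of class `nomogram`.
#' @export
build_nomogram <- function(scores, proteinuria, is_case) {
  ok <- stats::complete.cases(scores, proteinuria, is_case)
  scores <- scores[ok]; proteinuria <- proteinuria[ok]
  is_case <- as.logical(is_case[ok])
  if (stats::sd(scores) == 0 || stats::sd(proteinuria) == 0)
    stop("constant predictor")
  # near-separable inputs trigger glm convergence warnings; flag instead
  fit <- suppressWarnings(stats::glm(is_case ~ scores + proteinuria,
                                     family = stats::binomial()))
  separation <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 15)
  lp <- drop(stats::predict(fit, type = "link"))
  beta <- stats::coef(fit)
  contrib <- c(abs(beta["scores"]) * diff(range(scores)),
               abs(beta["proteinuria"]) * diff(range(proteinuria)))
  points <- 100 * contrib / max(contrib)
  cmp_score <- delong_ci_and_test(lp, scores, is_case)
  cmp_prot <- delong_ci_and_test(lp, proteinuria, is_case)
  structure(list(coefficients = beta,
                 points_scale = stats::setNames(points,
                                                c("score", "proteinuria")),
                 linear_predictor = lp,
                 auc_combined = auc(lp[is_case], lp[!is_case]),
                 auc_score = auc(scores[is_case], scores[!is_case]),
                 auc_proteinuria = auc(proteinuria[is_case],
                                       proteinuria[!is_case]),
                 vs_score = cmp_score, vs_proteinuria = cmp_prot,
                 separation = separation, n = length(lp)),
            class = "nomogram")
}

#' @export
print.nomogram <- function(x, ...) {
  cat("nomogram (logistic): AUC combined", round(x$auc_combined, 3),
      "| score alone", round(x$auc_score, 3),
      "| proteinuria alone", round(x$auc_proteinuria, 3), "\n")
  invisible(x)
}

#' Baseline-characteristics hypothesis tests
#'
#' The three tests conventionally used for cohort tables: Student's t test
#' for normally distributed continuous variables (raw vectors), the
#' Mann-Whitney / Wilcoxon rank-sum test for skewed continuous variables
#' (raw vectors), and the chi-squared test with Yates continuity correction
#' for categorical variables (a 2x2 count matrix, groups in rows).
#'
#' @param a,b raw value vectors for the continuous kinds; for
#'   `"categorical"`, `a` is the 2x2 matrix and `b` must be missing.
#' @param kind `"normal"`, `"skewed"` or `"categorical"`.
#' @return two-sided p-value.
#' @export
cohort_table_stats <- function(a, b = NULL,
                               kind = c("normal", "skewed", "categorical")) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    if (!is.null(b)) stop("categorical kind takes a single 2x2 count matrix")
    a <- as.matrix(a)
    if (!all(dim(a) == c(2, 2)) || any(a < 0))
      stop("categorical input must be a nonnegative 2x2 count matrix")
    if (stats::sd(prop.table(a, 1)[, 1]) == 0) return(1)
    return(stats::chisq.test(a, correct = TRUE)$p.value)
  }
  if (is.null(b)) stop(kind, " kind requires two raw value vectors")
  if (kind == "normal")
    return(stats::t.test(a, b, var.equal = TRUE)$p.value)
  wilcoxon_rank_sum(a, b)
}
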