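#' SVM hyperparameter settings
#'
#' The panel classifier is a soft-margin linear support vector machine: the
#' interpretable default for high-dimensional, low-sample-size peptide
#' panels. `C` is the box constraint on the dual coefficients (the cost of
#' margin violations).
#'
#' @param C regularization constant, `> 0`.
#' @return list of hyperparameters.
#' @export
panel_hyper <- function(C = 1) {
  stopifnot(is.numeric(C), C > 0)
  list(C = C)
}

## Exact soft-margin linear SVM via the dual quadratic program.
## quadprog::solve.QP (with a small ridge for positive definiteness)
## identifies the active set; the free dual variables and the intercept are
## then polished by solving the ridge-free KKT system exactly, so the
## decision function is deterministic and invariant to sample order.
svm_solve <- function(Z, y, C) {
  n <- nrow(Z)
  K <- tcrossprod(Z)
  Q <- (y %o% y) * K
  ridge <- 1e-4 * max(1, max(diag(K)))
  Amat <- cbind(y, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(Q + diag(ridge, n), rep(1, n), Amat, bvec, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), C)
  eps <- 1e-6 * C
  free <- alpha > eps & alpha < C - eps
  b <- NULL
  if (any(free)) {
    # KKT stationarity on the free set: Q_FF a_F + Q_FB a_B + nu y_F = 1,
    # y_F' a_F = -y_B' a_B; the multiplier nu of the equality constraint is
    # the intercept b. Exact solve removes the ridge bias.
    Fi <- which(free)
    aB <- ifelse(alpha >= C - eps, C, 0)
    aB[Fi] <- 0
    M <- rbind(cbind(Q[Fi, Fi, drop = FALSE], y[Fi]), c(y[Fi], 0))
    rhs <- c(1 - drop(Q[Fi, , drop = FALSE] %*% aB), -sum(y * aB))
    pol <- tryCatch(solve(M, rhs), error = function(e)
      tryCatch(qr.solve(M, rhs, tol = 1e-12), error = function(e) NULL))
    if (!is.null(pol) &&
        all(pol[seq_along(Fi)] > -eps & pol[seq_along(Fi)] < C + eps)) {
      alpha <- aB
      alpha[Fi] <- pmin(pmax(pol[seq_along(Fi)], 0), C)
      b <- pol[length(pol)]
    }
  }
  w <- drop(crossprod(Z, alpha * y))
  f <- drop(Z %*% w)
  if (is.null(b) && any(free)) b <- mean(y[free] - f[free])
  if (is.null(b)) {
    # all multipliers at bounds: b lies in the KKT-feasible interval
    lo <- c((1 - f)[y > 0 & alpha <= eps], (-1 - f)[y < 0 & alpha >= C - eps])
    up <- c((1 - f)[y > 0 & alpha >= C - eps], (-1 - f)[y < 0 & alpha <= eps])
    lo <- if (length(lo)) max(lo) else -Inf
    up <- if (length(up)) min(up) else Inf
    b <- if (is.finite(lo) && is.finite(up)) (lo + up) / 2 else
      if (is.finite(lo)) lo else if (is.finite(up)) up else 0
  }
  list(w = w, b = b, alpha = alpha)
}

## ln(1 + x) then center/scale with the supplied constants.
transform_block <- function(X, center, scale) {
  Z <- log1p(X)
  sweep(sweep(Z, 2, center, "-"), 2, scale, "/")
}

#' Fit the linear SVM panel classifier
#'
#' Restricts the dataset to the requested features, transforms intensities
#' by `ln(1 + x)` (keeping non-detections finite), centers and scales each
#' feature on the training data, and fits a soft-margin linear
#' maximal-margin classifier separating `case_group` (scored positive) from
#' all other samples present. Everything needed to score new samples
#' identically — feature order, transform constants, hyperplane — is stored
#' in the returned object. The diagnosis cutoff is left unset; see
#' [youden_cutoff()] and [set_panel_cutoff()].
#'
#' @param data an [intensity_dataset()] holding the training samples
#'   (typically the pFSGS and sFSGS arms).
#' @param features character vector of peptide ids to combine.
#' @param case_group the positive class label (default `"pFSGS"`).
#' @param hyper hyperparameters from [panel_hyper()].
#' @return object of class `trained_panel`.
#' @export
fit_svm <- function(data, features, case_group = "pFSGS",
                    hyper = panel_hyper()) {
  stopifnot(inherits(data, "intensity_dataset"))
  if (length(features) == 0) stop("empty feature set")
  missing_f <- setdiff(features, colnames(data$intensities))
  if (length(missing_f) > 0)
    stop("feature(s) absent from data: ", paste(missing_f, collapse = ", "))
  y <- ifelse(data$group == case_group, 1, -1)
  if (length(unique(y)) < 2) stop("training data holds a single class")
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  X <- data$intensities[, features, drop = FALSE]
  L <- log1p(X)
  center <- colMeans(L)
  scale <- apply(L, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  Z <- transform_block(X, center, scale)
  fit <- svm_solve(Z, y, hyper$C)
  structure(list(features = features, center = center, scale = scale,
                 w = stats::setNames(fit$w, features), b = fit$b,
                 hyper = hyper, case_group = case_group, cutoff = NULL,
                 meta = list(n_case = sum(y == 1), n_control = sum(y == -1))),
            class = "trained_panel")
}

#' @export
print.trained_panel <- function(x, ...) {
  cat("trained_panel:", length(x$features), "peptides, linear SVM (C =",
      x$hyper$C, ")\n")
  cat("cutoff:", if (is.null(x$cutoff)) "<unset>" else x$cutoff, "\n")
  invisible(x)
}

#' Score samples with a trained panel
#'
#' Applies the stored transform and hyperplane to produce one scalar score
#' per sample; samples scoring at or above the stored cutoff are classified
#' as the case group. Panel peptides absent from the dataset are treated as
#' not detected (intensity 0) and flagged with a warning.
#'
#' @param panel a `trained_panel`.
#' @param data an [intensity_dataset()].
#' @return data.frame with `sample_id`, `score` and (when a cutoff is set)
#'   logical `classified_case`.
#' @export
score_samples <- function(panel, data) {
  stopifnot(inherits(panel, "trained_panel"),
            inherits(data, "intensity_dataset"))
  have <- intersect(panel$features, colnames(data$intensities))
  X <- matrix(0, nrow(data$intensities), length(panel$features),
              dimnames = list(rownames(data$intensities), panel$features))
  X[, have] <- data$intensities[, have]
  miss <- setdiff(panel$features, have)
  if (length(miss) > 0)
    warning(length(miss), " panel peptide(s) absent from data, scored as 0: ",
            paste(utils::head(miss, 5), collapse = ", "))
  Z <- transform_block(X, panel$center, panel$scale)
  score <- drop(Z %*% panel$w) + panel$b
  out <- data.frame(sample_id = rownames(data$intensities), score = score,
                    stringsAsFactors = FALSE)
  if (!is.null(panel$cutoff)) out$classified_case <- score >= panel$cutoff
  out
}

#' Leave-one-out cross-validated panel scores
#'
#' For each sample, a panel is fitted on all other samples — with the
#' `ln(1+x)` centering/scaling constants re-estimated inside the fold, so
#' no information about the held-out sample leaks into its score — and the
#' held-out sample is scored by that fold's model.
#'
#' @inheritParams fit_svm
#' @return object of class `cv_record`: data.frame with `sample_id`,
#'   `is_case` and held-out `score`.
#' @export
loo_cv_scores <- function(data, features, case_group = "pFSGS",
                          hyper = panel_hyper()) {
  stopifnot(inherits(data, "intensity_dataset"))
  y <- data$group == case_group
  if (sum(y) < 3 || sum(!y) < 3)
    stop("leave-one-out CV needs at least 3 samples per class")
  n <- nrow(data$intensities)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    fold <- subset_dataset(data, samples = setdiff(seq_len(n), i))
    fit <- fit_svm(fold, features, case_group, hyper)
    held <- subset_dataset(data, samples = i)
    scores[i] <- score_samples(fit, held)$score
  }
  structure(data.frame(sample_id = rownames(data$intensities),
                       is_case = y, score = scores,
                       stringsAsFactors = FALSE),
            class = c("cv_record", "data.frame"))
}

## LOO-CV AUC of a feature subset (helper for the elimination loop).
loo_auc <- function(data, features, case_group, hyper) {
  cv <- loo_cv_scores(data, features, case_group, hyper)
  auc(cv$score[cv$is_case], cv$score[!cv$is_case])
}

#' Greedy backward feature elimination by cross-validated AUC
#'
#' The "take-one-out" panel optimization: at each round, the leave-one-out
#' CV AUC of the panel without each remaining peptide is computed, and the
#' peptide whose removal yields the largest AUC is dropped. Under the
#' default `"non_decreasing"` rule, a removal is accepted whenever it does
#' not reduce the current AUC (beyond `tol`), and elimination stops only
#' when every single removal strictly reduces performance — the behaviour
#' behind a published-size panel reduction where many peptides can be shed
#' before "further reduction ... reduced performance". The `"strict"` rule
#' instead stops as soon as no removal strictly improves the AUC. Ties
#' among near-equal removals are broken toward the peptide with the
#' largest stage-2 p-value when `p_step2` is supplied.
#'
#' @inheritParams fit_svm
#' @param p_step2 optional named numeric vector of stage-2 p-values used as
#'   tie-breaker.
#' @param tol AUC change below which two panels count as equivalent.
#' @param mode stopping rule, `"non_decreasing"` (default) or `"strict"`.
#' @return list with `features` (the survivors, original order preserved)
#'   and `trace` (data.frame of rounds: peptide removed, AUC after
#'   removal).
#' @export
take_one_out_elimination <- function(data, features, case_group = "pFSGS",
                                     hyper = panel_hyper(), p_step2 = NULL,
                                     tol = 1e-6,
                                     mode = c("non_decreasing", "strict")) {
  mode <- match.arg(mode)
  if (length(features) < 2) {
    if (length(features) < 1) stop("need at least one feature")
    return(list(features = features,
                trace = data.frame(round = integer(0), removed = character(0),
                                   auc_after = numeric(0))))
  }
  current <- features
  base_auc <- loo_auc(data, current, case_group, hyper)
  trace <- data.frame(round = 0L, removed = NA_character_,
                      auc_after = base_auc, stringsAsFactors = FALSE)
  round_i <- 0L
  while (length(current) > 1) {
    aucs <- vapply(seq_along(current), function(k)
      loo_auc(data, current[-k], case_group, hyper), numeric(1))
    best <- max(aucs)
    if (mode == "strict" && best <= base_auc + tol) break
    if (mode == "non_decreasing" && best < base_auc - tol) break
    cand <- which(aucs >= best - tol)
    drop_k <- if (length(cand) > 1 && !is.null(p_step2)) {
      pv <- p_step2[current[cand]]
      pv[is.na(pv)] <- -Inf
      cand[which.max(pv)]
    } else cand[1]
    round_i <- round_i + 1L
    trace <- rbind(trace, data.frame(round = round_i,
                                     removed = current[drop_k],
                                     auc_after = aucs[drop_k],
                                     stringsAsFactors = FALSE))
    base_auc <- aucs[drop_k]
    current <- current[-drop_k]
  }
  list(features = current, trace = trace)
}

#' Youden-index diagnosis cutoff
#'
#' Maximizes J = sensitivity + specificity - 1 over thresholds placed
#' midway between consecutive distinct observed scores (plus one threshold
#' below and above all scores). Ties in J are broken toward higher
#' specificity, then toward the higher threshold. Classification convention:
#' score `>= cutoff` calls the case class.
#'
#' @param case_scores,control_scores held-out scores of the two classes.
#' @return list with `cutoff`, `j`, `sensitivity` and `specificity`
#'   (proportions in `[0, 1]`), and `sensitivity_pct` / `specificity_pct`
#'   (percent, one decimal — the conventional reporting form).
#' @export
youden_cutoff <- function(case_scores, control_scores) {
  if (length(case_scores) == 0 || length(control_scores) == 0)
    stop("both classes must be present")
  s <- sort(unique(c(case_scores, control_scores)))
  cand <- if (length(s) == 1) s else
    c(s[1] - 1, (s[-length(s)] + s[-1]) / 2, s[length(s)] + 1)
  sens <- vapply(cand, function(t) mean(case_scores >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(control_scores < t), numeric(1))
  j <- sens + spec - 1
  ord <- order(-j, -spec, -cand)
  i <- ord[1]
  list(cutoff = cand[i], j = j[i],
       sensitivity = sens[i], specificity = spec[i],
       sensitivity_pct = round(100 * sens[i], 1),
       specificity_pct = round(100 * spec[i], 1))
}

#' Store a diagnosis cutoff on a trained panel
#'
#' Selects the Youden cutoff from held-out (cross-validated) scores and
#' stores it on the panel, completing the deployable classifier.
#'
#' @param panel a `trained_panel`.
#' @param cv a `cv_record` from [loo_cv_scores()] (or any data.frame with
#'   `is_case` and `score`).
#' @return the panel with `cutoff` set and the CV summary in `meta`.
#' @export
set_panel_cutoff <- function(panel, cv) {
  stopifnot(inherits(panel, "trained_panel"))
  yc <- youden_cutoff(cv$score[cv$is_case], cv$score[!cv$is_case])
  panel$cutoff <- yc$cutoff
  panel$meta$cv <- list(
    auc = auc(cv$score[cv$is_case], cv$score[!cv$is_case]),
    sensitivity = yc$sensitivity, specificity = yc$specificity)
  panel
}

#' Serialize / restore a trained panel as JSON
#'
#' The JSON carries every constant needed to score new samples identically:
#' feature order, per-feature transform constants, hyperplane weights,
#' intercept, cutoff and metadata.
#'
#' @param panel a `trained_panel`.
#' @param path output / input file path.
#' @return `write_panel` returns `path` invisibly; `read_panel` returns the
#'   restored `trained_panel`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "trained_panel"))
  obj <- unclass(panel)
  obj$center <- as.list(obj$center); obj$scale <- as.list(obj$scale)
  obj$w <- as.list(obj$w)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  structure(list(features = obj$features,
                 center = unlist(obj$center), scale = unlist(obj$scale),
                 w = unlist(obj$w), b = obj$b, hyper = obj$hyper,
                 case_group = obj$case_group,
                 cutoff = obj$cutoff, meta = obj$meta),
            class = "trained_panel")
}
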