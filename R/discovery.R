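#' Two-sided Wilcoxon rank-sum test p-value
#'
#' The workhorse test of the discovery filter. When both samples have at
#' most 10 observations and there are no ties, the p-value comes from exact
#' enumeration of the rank-sum null distribution; otherwise a normal
#' approximation with mid-rank tie correction of the variance and a
#' continuity correction is used. Non-detections (zeros) simply enter as
#' tied observations at 0.
#'
#' @param x,y numeric vectors of intensities for the two groups; both
#'   non-empty.
#' @return two-sided p-value in `(0, 1]`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U of x
  ties <- table(r)
  if (n1 <= 10 && n2 <= 10 && !any(ties > 1)) {
    p <- 2 * min(stats::pwilcox(u, n1, n2),
                 stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE))
    return(min(1, p))
  }
  mu <- n1 * n2 / 2
  n <- n1 + n2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)     # continuity correction
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up adjustment (the default false-discovery-rate
#' control used for the stage-1 screen), or Bonferroni.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @return vector of adjusted p-values, same order as `p`; each adjusted
#'   value is `>=` its raw value and the ranking of p-values is preserved.
#' @export
bh_adjust <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  if (method == "bonferroni") return(pmin(1, p * m))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  # step-up: running minimum of m/i * p_(i) from the largest p downwards
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Stage-1 biomarker screen: pFSGS versus normal controls
#'
#' Tests every peptide for differential abundance between primary FSGS and
#' normal-control samples with the Wilcoxon rank-sum test, adjusts across
#' all tested peptides, and flags peptides with adjusted p below `alpha` as
#' stage-1 candidates. The direction of change is the sign of the group
#' mean (or median) difference, pFSGS minus NC.
#'
#' @param data an [intensity_dataset()] containing pFSGS and NC samples.
#' @param alpha candidate threshold on the adjusted p-value.
#' @param adjust multiplicity adjustment, see [bh_adjust()].
#' @param direction_stat `"mean"` (default, matching the reported group
#'   mean intensities) or `"median"`.
#' @param min_detection optional minimum fraction of samples (across the
#'   two compared groups) in which a peptide must be detected to be tested;
#'   `0` disables the filter (default).
#' @return object of class `discovery_result`: a data.frame with one row
#'   per peptide (p-values, direction, group means, candidate status).
#' @export
step1_screen <- function(data, alpha = 0.05, adjust = "BH",
                         direction_stat = c("mean", "median"),
                         min_detection = 0) {
  stopifnot(inherits(data, "intensity_dataset"))
  direction_stat <- match.arg(direction_stat)
  cmp <- two_group_tests(data, "pFSGS", "NC", direction_stat, min_detection)
  res <- data.frame(peptide_id = colnames(data$intensities),
                    p_step1_raw = cmp$p,
                    p_step1_adj = NA_real_,
                    dir_step1 = cmp$dir,
                    mean_pfsgs = cmp$stat_a,
                    mean_nc = cmp$stat_b,
                    stringsAsFactors = FALSE)
  tested <- !is.na(res$p_step1_raw)
  res$p_step1_adj[tested] <- bh_adjust(res$p_step1_raw[tested], method = adjust)
  res$status <- ifelse(!tested, "excluded",
                       ifelse(res$p_step1_adj < alpha, "candidate_step1",
                              "excluded"))
  res$reason <- ifelse(!tested, "low_detection",
                       ifelse(res$status == "candidate_step1", "",
                              "step1_not_significant"))
  structure(res, class = c("discovery_result", "data.frame"),
            alpha = alpha, direction_stat = direction_stat)
}

#' Stages 2-3: direction-consistent confirmation
#'
#' Each stage-1 candidate is re-tested (unadjusted Wilcoxon) in two further
#' comparisons, pFSGS vs sFSGS and pFSGS vs other CKD. A candidate is
#' retained only if both tests reach `alpha` and the direction of change
#' (up- or downregulated in pFSGS) is identical in all three comparisons;
#' all other candidates are marked excluded with the first failing reason.
#'
#' @param result a `discovery_result` from [step1_screen()].
#' @param data the same [intensity_dataset()], which must also contain
#'   sFSGS and CKD samples.
#' @param alpha per-test threshold for the unadjusted stage-2/3 p-values.
#' @return the augmented `discovery_result` with columns `p_step2`,
#'   `p_step3`, per-stage directions, comparator means and final `status`
#'   (`retained_final` or `excluded` + `reason`).
#' @export
directional_filter <- function(result, data, alpha = 0.05) {
  stopifnot(inherits(result, "discovery_result"),
            inherits(data, "intensity_dataset"))
  direction_stat <- attr(result, "direction_stat") %||% "mean"
  cand <- result$status == "candidate_step1"
  s2 <- two_group_tests(data, "pFSGS", "sFSGS", direction_stat, 0,
                        peptides = result$peptide_id[cand])
  s3 <- two_group_tests(data, "pFSGS", "CKD_other", direction_stat, 0,
                        peptides = result$peptide_id[cand])
  result$p_step2 <- result$p_step3 <- NA_real_
  result$dir_step2 <- result$dir_step3 <- NA_character_
  result$mean_sfsgs <- result$mean_ckd <- NA_real_
  result$p_step2[cand] <- s2$p
  result$p_step3[cand] <- s3$p
  result$dir_step2[cand] <- s2$dir
  result$dir_step3[cand] <- s3$dir
  result$mean_sfsgs[cand] <- s2$stat_b
  result$mean_ckd[cand] <- s3$stat_b
  reason <- character(sum(cand))
  ok2 <- s2$p < alpha
  ok3 <- s3$p < alpha
  same_dir <- s2$dir == result$dir_step1[cand] &
    s3$dir == result$dir_step1[cand] & result$dir_step1[cand] != "none"
  reason[!ok2] <- "step2_not_significant"
  reason[ok2 & !ok3] <- "step3_not_significant"
  reason[ok2 & ok3 & !same_dir] <- "direction_mismatch"
  retained <- ok2 & ok3 & same_dir
  result$status[cand] <- ifelse(retained, "retained_final", "excluded")
  result$reason[cand] <- reason
  attr(result, "alpha23") <- alpha
  result
}

#' Run the full three-stage discovery filter
#'
#' Convenience wrapper: [step1_screen()] followed by [directional_filter()].
#'
#' @inheritParams step1_screen
#' @param alpha1 adjusted-p threshold for stage 1.
#' @param alpha23 unadjusted-p threshold for stages 2 and 3.
#' @return a `discovery_result`.
#' @export
run_discovery <- function(data, alpha1 = 0.05, alpha23 = 0.05,
                          adjust = "BH", direction_stat = "mean",
                          min_detection = 0) {
  res <- step1_screen(data, alpha = alpha1, adjust = adjust,
                      direction_stat = direction_stat,
                      min_detection = min_detection)
  directional_filter(res, data, alpha = alpha23)
}

#' Peptide ids retained by the discovery filter
#'
#' @param result a `discovery_result`.
#' @return character vector of retained peptide ids.
#' @export
retained_peptides <- function(result) {
  stopifnot(inherits(result, "discovery_result"))
  result$peptide_id[result$status == "retained_final"]
}

## Per-peptide rank tests between two cohort groups; returns p, direction
## and the per-group location statistic. `min_detection` marks peptides
## detected in too few samples as untested (p = NA).
two_group_tests <- function(data, group_a, group_b, direction_stat,
                            min_detection, peptides = NULL) {
  ia <- which(data$group == group_a)
  ib <- which(data$group == group_b)
  if (length(ia) == 0) stop("no samples in group ", group_a)
  if (length(ib) == 0) stop("no samples in group ", group_b)
  m <- data$intensities
  if (!is.null(peptides)) m <- m[, peptides, drop = FALSE]
  locfun <- if (direction_stat == "mean") colMeans else
    function(x) apply(x, 2, stats::median)
  stat_a <- locfun(m[ia, , drop = FALSE])
  stat_b <- locfun(m[ib, , drop = FALSE])
  p <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) p[j] <- wilcoxon_rank_sum(m[ia, j], m[ib, j])
  if (min_detection > 0) {
    detected <- colMeans(m[c(ia, ib), , drop = FALSE] > 0)
    p[detected < min_detection] <- NA_real_
  }
  d <- stat_a - stat_b
  list(p = p, stat_a = stat_a, stat_b = stat_b,
       dir = ifelse(d > 0, "up", ifelse(d < 0, "down", "none")))
}
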