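#' Configuration of the synthetic CE-MS cohort generator
#'
#' The simulator emulates a normalized urinary CE-MS peptidome: each
#' peptide/sample intensity is a zero-inflated log-normal draw. A peptide is
#' detected in a sample of group \eqn{g} with probability \eqn{\pi_g}; when
#' detected, its intensity is log-normal with log-location \eqn{\mu_g} and a
#' shared log-scale spread \eqn{\sigma}, so the group mean is
#' \eqn{\pi_g e^{\mu_g + \sigma^2/2}}. Clinical covariates are drawn from
#' the packaged per-group summary statistics (normal for mean/SD variables,
#' log-normal matched to median/IQR for the skewed ones, Bernoulli for
#' counts, truncated normal on \[0, 100\] for IFTA).
#'
#' Defaults mirror the cohorts the panel was defined on: training arms of
#' 19 primary FSGS, 44 secondary FSGS, 98 normal controls and 100 other-CKD
#' patients; an independent specificity set of 110 NC and 170 CKD; 4000
#' non-discriminatory background peptides so that discovery runs in a
#' realistic multiple-testing regime.
#'
#' @param group_sizes named integer vector of training-arm sizes.
#' @param independent_sizes named integer vector for the independent set
#'   (non-pFSGS groups only).
#' @param n_background number of background (group-invariant) peptides.
#' @param sigma shared log-scale spread of detected intensities
#'   (natural-log units).
#' @param m0 detection half-saturation constant: a peptide with group mean
#'   `m` is detected with probability `m / (m + m0)`.
#' @param background list with `meanlog`, `sdlog` of the log-normal from
#'   which each background peptide's overall mean intensity is drawn, and
#'   optionally `pi` to force a fixed detection probability.
#' @param covariate_summaries per-group clinical summaries; defaults to the
#'   packaged table (see [load_cohort_summaries()]).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(pFSGS = 19L, sFSGS = 44L,
                                          NC = 98L, CKD_other = 100L),
                          independent_sizes = c(NC = 110L, CKD_other = 170L),
                          n_background = 4000L,
                          sigma = 1.0,
                          m0 = 50,
                          background = list(meanlog = log(200), sdlog = 2,
                                            pi = NULL),
                          covariate_summaries = load_cohort_summaries()) {
  stopifnot(all(group_sizes >= 0), all(independent_sizes >= 0),
            n_background >= 0, sigma >= 0, m0 > 0)
  if (!all(names(group_sizes) %in% GROUP_LEVELS))
    stop("group_sizes names must be cohort labels")
  structure(list(group_sizes = group_sizes,
                 independent_sizes = independent_sizes,
                 n_background = as.integer(n_background),
                 sigma = sigma, m0 = m0, background = background,
                 covariate_summaries = covariate_summaries),
            class = "cohort_config")
}

#' Calibrate per-peptide generator parameters to panel group means
#'
#' For each panel peptide and group, chooses the detection probability
#' \eqn{\pi_g} and the log-location \eqn{\mu_g} so that the analytic
#' zero-inflated log-normal mean \eqn{\pi_g e^{\mu_g + \sigma^2/2}} equals
#' the panel's printed mean intensity exactly. The detection rule ties
#' detection frequency to abundance, \eqn{\pi_g = \min(1, m/(m + m_0))},
#' reflecting that low-abundance peptides fall below the detection limit in
#' a fraction of profiles; a group mean of exactly 0 forces \eqn{\pi_g = 0}.
#'
#' @param panel panel data.frame (see [load_panel_fixture()]).
#' @param sigma shared log-scale spread, `> 0`.
#' @param m0 detection half-saturation constant.
#' @return object of class `generator_specs`: list with `peptide_id` and
#'   peptides x groups matrices `pi` and `mu`, plus `sigma`.
#' @export
calibrate_from_panel <- function(panel, sigma = 1.0, m0 = 50) {
  validate_panel(panel)
  stopifnot(sigma > 0, m0 > 0)
  means <- cbind(pFSGS = panel$mean_pfsgs, sFSGS = panel$mean_sfsgs,
                 NC = panel$mean_nc, CKD_other = panel$mean_ckd)
  pi <- ifelse(means == 0, 0, pmin(1, means / (means + m0)))
  mu <- matrix(0, nrow(means), ncol(means), dimnames = dimnames(pi))
  pos <- means > 0
  mu[pos] <- log(means[pos] / pi[pos]) - sigma^2 / 2
  structure(list(peptide_id = panel$peptide_id, pi = pi, mu = mu,
                 sigma = sigma),
            class = "generator_specs")
}

#' Analytic group means implied by generator specs
#'
#' Inverse of the calibration: returns the peptides x groups matrix of
#' expected intensities \eqn{\pi_g e^{\mu_g + \sigma^2/2}}.
#'
#' @param specs a `generator_specs` object.
#' @return numeric matrix.
#' @export
spec_group_means <- function(specs) {
  stopifnot(inherits(specs, "generator_specs"))
  m <- specs$pi * exp(specs$mu + specs$sigma^2 / 2)
  m[specs$pi == 0] <- 0
  rownames(m) <- specs$peptide_id
  m
}

#' Generate a seeded synthetic CE-MS cohort
#'
#' Draws a full intensity dataset: calibrated panel peptides (group-specific
#' parameters from `specs`) plus `config$n_background` background peptides
#' whose parameters are drawn once per peptide and shared across groups, so
#' they carry no signal. Clinical covariates are simulated per group from
#' the configured summaries; other-CKD samples receive an etiology subcode
#' drawn with the packaged etiology frequencies. Identical
#' `(config, specs, seed)` produce bit-identical datasets; the caller's RNG
#' state is left untouched.
#'
#' @param config a [cohort_config()].
#' @param specs a `generator_specs` object (may be `NULL` for a
#'   background-only cohort).
#' @param seed integer RNG seed; mandatory.
#' @param cohort `"training"` (all four arms) or `"independent"`
#'   (`config$independent_sizes`, non-pFSGS arms only).
#' @return an [intensity_dataset()].
#' @export
generate_cohort <- function(config, specs = NULL, seed,
                            cohort = c("training", "independent")) {
  stopifnot(inherits(config, "cohort_config"))
  if (missing(seed) || is.null(seed))
    stop("a seed is required: cohort generation must be reproducible")
  cohort <- match.arg(cohort)
  sizes <- if (cohort == "training") config$group_sizes else
    config$independent_sizes
  sizes <- sizes[sizes > 0]
  with_seed(seed, {
    groups <- rep(names(sizes), sizes)
    ids <- sprintf("%s_%s_%03d", if (cohort == "training") "tr" else "ind",
                   groups, unlist(lapply(sizes, seq_len)))
    n <- length(ids)

    cols <- list()
    if (!is.null(specs)) {
      stopifnot(inherits(specs, "generator_specs"))
      p <- length(specs$peptide_id)
      panel_m <- matrix(0, n, p, dimnames = list(ids, specs$peptide_id))
      for (g in names(sizes)) {
        rows <- which(groups == g)
        for (j in seq_len(p)) {
          pij <- specs$pi[j, g]
          if (pij == 0) next
          det <- stats::rbinom(length(rows), 1, pij)
          panel_m[rows, j] <- det *
            stats::rlnorm(length(rows), specs$mu[j, g], specs$sigma)
        }
      }
      cols$panel <- panel_m
    }
    if (config$n_background > 0) {
      nb <- config$n_background
      bg_mean <- stats::rlnorm(nb, config$background$meanlog,
                               config$background$sdlog)
      bg_pi <- if (!is.null(config$background$pi))
        rep(config$background$pi, nb) else bg_mean / (bg_mean + config$m0)
      bg_mu <- ifelse(bg_pi > 0, log(bg_mean / pmax(bg_pi, 1e-300)) -
                        config$sigma^2 / 2, 0)
      bg <- matrix(0, n, nb,
                   dimnames = list(ids, sprintf("bg%04d", seq_len(nb))))
      for (j in seq_len(nb)) {
        if (bg_pi[j] == 0) next
        det <- stats::rbinom(n, 1, bg_pi[j])
        bg[, j] <- det * stats::rlnorm(n, bg_mu[j], config$sigma)
      }
      cols$bg <- bg
    }
    if (length(cols) == 0) stop("nothing to generate: no specs and no background")
    m <- do.call(cbind, unname(cols))

    covariates <- draw_covariates(groups, config$covariate_summaries)
    etiology <- rep(NA_character_, n)
    if ("CKD_other" %in% groups) {
      tab <- load_etiology_fixture(if (cohort == "training") "discovery"
                                   else "independent")
      rows <- which(groups == "CKD_other")
      pool <- rep(tab$code, tab$n)
      etiology[rows] <- if (length(rows) == length(pool)) pool else
        sample(tab$code, length(rows), replace = TRUE, prob = tab$n)
    }
    intensity_dataset(m, groups, etiology = etiology, covariates = covariates)
  })
}

#' Generate a null cohort with no group effect anywhere
#'
#' Identical in structure to [generate_cohort()] but every peptide shares a
#' single `(pi, mu, sigma)` across all groups, so any apparent differential
#' abundance is sampling noise. Used to verify false-discovery control of
#' the discovery screen.
#'
#' @inheritParams generate_cohort
#' @return an [intensity_dataset()].
#' @export
generate_null_cohort <- function(config, seed,
                                 cohort = c("training", "independent")) {
  generate_cohort(config, specs = NULL, seed = seed, cohort = match.arg(cohort))
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

## Draw the clinical covariate block for a vector of group labels.
draw_covariates <- function(groups, summaries) {
  n <- length(groups)
  out <- data.frame(proteinuria = rep(NA_real_, n), eGFR = NA_real_,
                    age = NA_real_, sex = NA_character_, IFTA = NA_real_,
                    stringsAsFactors = FALSE)
  for (g in unique(groups)) {
    s <- summaries[[g]]
    if (is.null(s)) next
    rows <- which(groups == g)
    k <- length(rows)
    out$age[rows] <- stats::rnorm(k, s$age$mean, s$age$sd)
    out$sex[rows] <- ifelse(stats::rbinom(k, 1, s$sex_male$count / s$n) == 1,
                            "M", "F")
    out$eGFR[rows] <- rlnorm_iqr(k, s$eGFR)
    out$proteinuria[rows] <- rlnorm_iqr(k, s$proteinuria)
    if (!is.null(s$IFTA))
      out$IFTA[rows] <- rtruncnorm01(k, s$IFTA$mean, s$IFTA$sd, 0, 100)
  }
  out
}

## Log-normal draws matched to a median / quartile summary.
rlnorm_iqr <- function(k, s) {
  sdlog <- (log(s$q3) - log(s$q1)) / (2 * stats::qnorm(0.75))
  stats::rlnorm(k, meanlog = log(s$median), sdlog = max(sdlog, 1e-12))
}

## Truncated-normal draws by inverse-CDF (exact, no rejection loop).
rtruncnorm01 <- function(k, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(k) * (phi - plo), mean, sd)
}
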