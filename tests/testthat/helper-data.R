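# Shared fixture builders. Everything is generated in code; no binary data.

# A tiny deterministic dataset with all four cohort groups.
tiny_dataset <- function() {
  m <- matrix(c(10, 0, 3, 250,
                12, 1, 2, 300,
                0, 5, 2, 40,
                1, 6, 3, 50,
                0, 0, 2, 10,
                0, 1, 2, 12,
                2, 3, 2, 80,
                1, 2, 3, 90),
              nrow = 8, byrow = TRUE,
              dimnames = list(paste0("s", 1:8), paste0("pep", 1:4)))
  intensity_dataset(
    m, rep(c("pFSGS", "sFSGS", "NC", "CKD_other"), each = 2),
    etiology = c(NA, NA, NA, NA, NA, NA, "DNP", "IGANP"),
    covariates = data.frame(proteinuria = c(8, 9, 2, 3, 0.1, 0.2, 2, 4),
                            eGFR = c(50, 60, 30, 35, 90, 95, 40, 45),
                            age = c(45, 50, 60, 62, 44, 46, 45, 47),
                            sex = c("M", "F", "M", "M", "F", "M", "F", "M"),
                            IFTA = c(10, 15, 30, 25, NA, NA, 20, 15)))
}

# Separable two-class dataset on log-intensity scale: cases high, controls low.
separable_dataset <- function(n_case = 10, n_control = 12, p = 3,
                              delta = 4, seed = 42) {
  set.seed(seed)
  m <- exp(matrix(rnorm((n_case + n_control) * p, 4), ncol = p))
  m[seq_len(n_case), ] <- m[seq_len(n_case), ] * exp(delta)
  dimnames(m) <- list(sprintf("s%02d", seq_len(nrow(m))),
                      paste0("pep", seq_len(p)))
  intensity_dataset(m, rep(c("pFSGS", "sFSGS"), c(n_case, n_control)))
}

# Case/control dataset with k informative features and optional pure-noise
# features appended.
informative_dataset <- function(n_case, n_control, k_info, k_noise = 0,
                                delta = 1.5, seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  m <- exp(matrix(rnorm(n * (k_info + k_noise), 4), ncol = k_info + k_noise))
  m[seq_len(n_case), seq_len(k_info)] <-
    m[seq_len(n_case), seq_len(k_info)] * exp(delta)
  dimnames(m) <- list(sprintf("s%03d", seq_len(n)),
                      c(paste0("info", seq_len(k_info)),
                        if (k_noise > 0) paste0("noise", seq_len(k_noise))))
  intensity_dataset(m, rep(c("pFSGS", "sFSGS"), c(n_case, n_control)))
}

# Complementary block-signal panel: case i is elevated (by delta on the log
# scale) in exactly one of k informative peptides, so every informative
# peptide is individually load-bearing, plus one dense pure-noise peptide.
block_panel_dataset <- function(n_case = 12, n_control = 12, k = 3,
                                delta = 5, seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  m <- exp(matrix(rnorm(n * (k + 1), 4, 0.5), ncol = k + 1))
  for (i in seq_len(n_case))
    m[i, 1 + (i - 1) %% k] <- m[i, 1 + (i - 1) %% k] * exp(delta)
  dimnames(m) <- list(sprintf("s%03d", seq_len(n)),
                      c(paste0("info", seq_len(k)), "noise1"))
  intensity_dataset(m, rep(c("pFSGS", "sFSGS"), c(n_case, n_control)))
}

# Exhaustive-threshold Youden oracle: every observed score +/- epsilon.
youden_oracle <- function(cases, controls) {
  cand <- sort(unique(c(cases, controls)))
  cand <- sort(c(cand - 1e-9, cand + 1e-9))
  max(vapply(cand, function(t)
    mean(cases >= t) + mean(controls < t) - 1, numeric(1)))
}
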