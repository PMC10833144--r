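#' Load the packaged 93-peptide diagnostic panel
#'
#' Returns the pFSGS93 panel: 93 sequenced urinary peptides that
#' discriminate primary FSGS from secondary FSGS, normal controls (NC) and
#' other chronic kidney diseases (CKD). Each row carries the peptide id, the
#' amino-acid sequence (lowercase `p` = hydroxyproline, lowercase `m` =
#' oxidized methionine), the parental protein, the three discovery-stage
#' p-values (stage 1 pFSGS vs NC, multiplicity-adjusted; stages 2 and 3
#' pFSGS vs sFSGS and pFSGS vs CKD, unadjusted Wilcoxon), and the four
#' per-group mean signal intensities in arbitrary normalized units. Rows are
#' ordered by the stage-1 adjusted p-value.
#'
#' @return data.frame with 93 rows and columns `peptide_id`, `sequence`,
#'   `protein_name`, `p_step1`, `p_step2`, `p_step3`, `mean_pfsgs`,
#'   `mean_nc`, `mean_sfsgs`, `mean_ckd`.
#' @export
load_panel_fixture <- function() {
  path <- system.file("extdata", "panel_pfsgs93.tsv", package = "urinepanel",
                      mustWork = TRUE)
  panel <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  validate_panel(panel)
  panel
}

## Invariant checks shared by the fixture loader and user-supplied panels.
validate_panel <- function(panel) {
  need <- c("peptide_id", "sequence", "protein_name", "p_step1", "p_step2",
            "p_step3", "mean_pfsgs", "mean_nc", "mean_sfsgs", "mean_ckd")
  if (!all(need %in% names(panel)))
    stop("panel is missing column(s): ",
         paste(setdiff(need, names(panel)), collapse = ", "))
  if (anyDuplicated(panel$peptide_id)) stop("duplicate peptide_id in panel")
  if (!all(grepl("^[A-Zpm]+$", panel$sequence)))
    stop("panel sequence outside the [A-Zpm] alphabet")
  pv <- as.matrix(panel[c("p_step1", "p_step2", "p_step3")])
  if (any(pv <= 0 | pv > 1)) stop("panel p-values must lie in (0, 1]")
  mv <- as.matrix(panel[c("mean_pfsgs", "mean_nc", "mean_sfsgs", "mean_ckd")])
  if (any(mv < 0)) stop("panel mean intensities must be >= 0")
  invisible(panel)
}

#' Load a packaged CKD etiology table
#'
#' Etiology composition of the two non-FSGS CKD control cohorts: the
#' age-/sex-matched discovery set (n = 100) and the independent specificity
#' set (n = 170).
#'
#' @param which `"discovery"` or `"independent"`.
#' @return data.frame with columns `code`, `label`, `n`.
#' @export
load_etiology_fixture <- function(which = c("discovery", "independent")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("etiology_", which, ".json"),
                      package = "urinepanel", mustWork = TRUE)
  tab <- jsonlite::fromJSON(path)$entries
  tab$n <- as.integer(tab$n)
  tab
}

#' Total patient count of an etiology table
#'
#' @param table data.frame with an `n` column of per-etiology counts, as
#'   returned by [load_etiology_fixture()], or any user-supplied counts.
#' @return integer sum of `n`.
#' @export
etiology_table_total <- function(table) {
  n <- if (is.data.frame(table)) table$n else table
  if (length(n) == 0) return(0L)
  if (any(is.na(n)) || any(n < 0)) stop("etiology counts must be nonnegative")
  as.integer(sum(n))
}

#' Load the per-group clinical summary statistics
#'
#' Baseline characteristics of the four biomarker-definition cohorts
#' (primary FSGS n = 19, secondary FSGS n = 44, normal controls n = 98,
#' other CKD n = 100): sex, age, eGFR, proteinuria, interstitial fibrosis
#' and tubular atrophy (IFTA), and nephrotic-range proteinuria counts.
#' These summaries parameterise the covariate arm of the cohort simulator.
#'
#' @return named list, one entry per group.
#' @export
load_cohort_summaries <- function() {
  path <- system.file("extdata", "cohort_characteristics.json",
                      package = "urinepanel", mustWork = TRUE)
  jsonlite::fromJSON(path)$groups
}

#' Count panel peptides from a parental protein
#'
#' Matches `protein_substring` against the panel's protein names,
#' case-insensitively and on word boundaries, so that e.g.
#' `"Apolipoprotein A-I"` matches only A-I fragments and not A-IV ones,
#' while `"Collagen"` matches every collagen chain. An empty substring
#' matches everything.
#'
#' @param panel panel data.frame (see [load_panel_fixture()]).
#' @param protein_substring protein name or fragment thereof.
#' @return list with `count` (integer) and `fraction` (percent of the panel,
#'   rounded to one decimal).
#' @export
panel_protein_composition <- function(panel, protein_substring) {
  validate_panel(panel)
  if (nrow(panel) == 0) stop("panel is empty")
  hit <- protein_matches(panel$protein_name, protein_substring)
  count <- sum(hit)
  list(count = as.integer(count),
       fraction = round(100 * count / nrow(panel), 1))
}

protein_matches <- function(names, substring) {
  if (nchar(substring) == 0) return(rep(TRUE, length(names)))
  rx <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", substring), "\\b")
  grepl(rx, names, ignore.case = TRUE, perl = TRUE)
}

#' Maximum between-group fold change of a protein's panel peptides
#'
#' For every panel peptide whose parental protein matches
#' `protein_substring`, forms the ratio of mean intensities
#' `numerator_group / denominator_group` and returns the maximum. Peptides
#' whose denominator mean is exactly 0 (not detected in that group) are
#' skipped, so the ratio is always finite.
#'
#' @param panel panel data.frame.
#' @param protein_substring protein name fragment (word-boundary matched).
#' @param numerator_group,denominator_group one of `"pFSGS"`, `"NC"`,
#'   `"sFSGS"`, `"CKD_other"`.
#' @return list with `ratio` (maximum finite fold change), `rounded`
#'   (nearest integer, the conventional reporting form) and `peptide_id`
#'   (the peptide attaining it).
#' @export
max_group_fold_change <- function(panel, protein_substring,
                                  numerator_group, denominator_group) {
  validate_panel(panel)
  col_of <- c(pFSGS = "mean_pfsgs", NC = "mean_nc", sFSGS = "mean_sfsgs",
              CKD_other = "mean_ckd")
  numerator_group <- match.arg(numerator_group, names(col_of))
  denominator_group <- match.arg(denominator_group, names(col_of))
  hit <- protein_matches(panel$protein_name, protein_substring)
  if (!any(hit)) stop("no panel peptide matches '", protein_substring, "'")
  num <- panel[[col_of[numerator_group]]][hit]
  den <- panel[[col_of[denominator_group]]][hit]
  ids <- panel$peptide_id[hit]
  keep <- den > 0
  if (!any(keep))
    stop("no matching peptide has a nonzero ", denominator_group, " mean")
  ratios <- num[keep] / den[keep]
  i <- which.max(ratios)
  list(ratio = ratios[i], rounded = round(ratios[i]),
       peptide_id = ids[keep][i])
}
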