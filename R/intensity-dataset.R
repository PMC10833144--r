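#' @keywords internal
"_PACKAGE"

## Closed vocabulary of cohort labels used throughout the pipeline.
GROUP_LEVELS <- c("pFSGS", "sFSGS", "NC", "CKD_other")

## Reserved clinical covariate columns recognised in intensity files.
COVARIATE_COLS <- c("proteinuria", "eGFR", "age", "sex", "IFTA")

#' Construct a validated intensity dataset
#'
#' An `intensity_dataset` is the central container of the package: a
#' samples x peptides matrix of nonnegative CE-MS signal intensities
#' (arbitrary normalized amplitude units; 0 means "peptide not detected in
#' this sample"), a cohort label per sample, and optionally an etiology
#' subcode and clinical covariates.
#'
#' @param intensities numeric matrix, samples in rows, peptides in columns.
#'   Row names are sample ids, column names peptide ids; both mandatory and
#'   unique. All values must be finite and `>= 0`.
#' @param group character or factor of cohort labels, one per sample, drawn
#'   from `"pFSGS"`, `"sFSGS"`, `"NC"`, `"CKD_other"`.
#' @param etiology optional character vector of CKD etiology subcodes
#'   (e.g. `"DNP"`, `"IGANP"`); `NA` allowed.
#' @param covariates optional data.frame of clinical covariates with columns
#'   among `proteinuria` (g/d), `eGFR` (ml/min/1.73 m^2), `age` (years),
#'   `sex` (`"M"`/`"F"`), `IFTA` (percent).
#' @return object of class `intensity_dataset`.
#' @export
intensity_dataset <- function(intensities, group, etiology = NULL,
                              covariates = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    stop("intensity matrix must carry sample ids (rownames) and peptide ids (colnames)")
  if (anyDuplicated(rownames(intensities)))
    stop("duplicate sample_id: ",
         paste(unique(rownames(intensities)[duplicated(rownames(intensities))]),
               collapse = ", "))
  if (anyDuplicated(colnames(intensities)))
    stop("duplicate peptide_id: ",
         paste(unique(colnames(intensities)[duplicated(colnames(intensities))]),
               collapse = ", "))
  bad <- which(!is.finite(intensities) | intensities < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "invalid intensity at sample '%s', peptide '%s' (value %s): intensities must be finite and >= 0",
      rownames(intensities)[bad[1, 1]], colnames(intensities)[bad[1, 2]],
      format(intensities[bad[1, , drop = FALSE]])))
  group <- as.character(group)
  if (length(group) != nrow(intensities))
    stop("group labels must match the number of samples")
  unknown <- setdiff(unique(group), GROUP_LEVELS)
  if (length(unknown) > 0)
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(GROUP_LEVELS, collapse = ", "), ")")
  if (!is.null(etiology)) {
    etiology <- as.character(etiology)
    if (length(etiology) != nrow(intensities))
      stop("etiology must match the number of samples")
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(intensities))
      stop("covariates must have one row per sample")
    extra <- setdiff(names(covariates), COVARIATE_COLS)
    if (length(extra) > 0)
      stop("unrecognised covariate column(s): ", paste(extra, collapse = ", "))
    rownames(covariates) <- rownames(intensities)
  }
  structure(
    list(intensities = intensities,
         group = factor(group, levels = GROUP_LEVELS),
         etiology = etiology,
         covariates = covariates),
    class = "intensity_dataset")
}

#' @export
print.intensity_dataset <- function(x, ...) {
  cat("intensity_dataset:", nrow(x$intensities), "samples x",
      ncol(x$intensities), "peptides\n")
  print(table(droplevels(x$group)))
  if (!is.null(x$covariates))
    cat("covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.intensity_dataset <- function(x) dim(x$intensities)

#' Subset an intensity dataset by sample and/or peptide
#'
#' @param x an `intensity_dataset`.
#' @param samples,peptides index vectors (logical, integer or names); missing
#'   means keep all.
#' @return a new `intensity_dataset`.
#' @export
subset_dataset <- function(x, samples = NULL, peptides = NULL) {
  stopifnot(inherits(x, "intensity_dataset"))
  if (is.null(samples)) samples <- seq_len(nrow(x$intensities))
  if (is.null(peptides)) peptides <- seq_len(ncol(x$intensities))
  intensity_dataset(
    x$intensities[samples, peptides, drop = FALSE],
    as.character(x$group)[if (is.character(samples))
      match(samples, rownames(x$intensities)) else samples],
    etiology = if (!is.null(x$etiology))
      x$etiology[if (is.character(samples))
        match(samples, rownames(x$intensities)) else samples],
    covariates = if (!is.null(x$covariates))
      x$covariates[samples, , drop = FALSE])
}

#' Read an intensity dataset from tab-separated text
#'
#' Two layouts are supported. The default `"wide"` layout has one row per
#' sample: `sample_id`, `group`, then optionally `etiology` and any of the
#' clinical covariate columns (`proteinuria`, `eGFR`, `age`, `sex`, `IFTA`),
#' followed by one column per peptide. The `"long"` layout has columns
#' `sample_id`, `group`, `peptide_id`, `intensity`; sample/peptide pairs
#' absent from a long file are taken as 0 (not detected) only when
#' `sparse = TRUE`, otherwise an incomplete long file is an error.
#'
#' @param path file path of a UTF-8 TSV with a single header row.
#' @param dialect list of format options: `layout` (`"wide"` or `"long"`)
#'   and `sparse` (logical, long layout only).
#' @return an `intensity_dataset`.
#' @export
read_intensity_dataset <- function(path, dialect = list(layout = "wide",
                                                        sparse = FALSE)) {
  layout <- match.arg(dialect$layout %||% "wide", c("wide", "long"))
  sparse <- isTRUE(dialect$sparse)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (layout == "long") {
    need <- c("sample_id", "group", "peptide_id", "intensity")
    if (!all(need %in% names(df)))
      stop("long layout requires columns: ", paste(need, collapse = ", "))
    vals <- parse_intensity_column(df$intensity, df$sample_id, df$peptide_id)
    sids <- unique(df$sample_id)
    pids <- unique(df$peptide_id)
    m <- matrix(if (sparse) 0 else NA_real_, length(sids), length(pids),
                dimnames = list(sids, pids))
    m[cbind(match(df$sample_id, sids), match(df$peptide_id, pids))] <- vals
    if (anyNA(m))
      stop("long file does not cover all sample/peptide pairs; ",
           "declare dialect$sparse = TRUE for sparse encoding")
    grp <- df$group[match(sids, df$sample_id)]
    return(intensity_dataset(m, grp))
  }
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("wide layout requires 'sample_id' and 'group' columns")
  meta_cols <- intersect(c("sample_id", "group", "etiology", COVARIATE_COLS),
                         names(df))
  pep_cols <- setdiff(names(df), meta_cols)
  if (length(pep_cols) == 0) stop("no peptide columns found")
  m <- matrix(NA_real_, nrow(df), length(pep_cols),
              dimnames = list(df$sample_id, pep_cols))
  for (j in seq_along(pep_cols))
    m[, j] <- parse_intensity_column(df[[pep_cols[j]]], df$sample_id,
                                     pep_cols[j])
  cov <- intersect(COVARIATE_COLS, names(df))
  covariates <- NULL
  if (length(cov) > 0) {
    covariates <- df[cov]
    for (cc in setdiff(cov, "sex")) covariates[[cc]] <- as.numeric(covariates[[cc]])
  }
  intensity_dataset(m, df$group,
                    etiology = if ("etiology" %in% names(df))
                      ifelse(df$etiology == "", NA_character_, df$etiology),
                    covariates = covariates)
}

## Parse an intensity column strictly, naming the offending cell on failure.
parse_intensity_column <- function(x, sample_ids, peptide_id) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad) > 0)
    stop(sprintf("unparseable intensity '%s' at sample '%s', peptide '%s'",
                 x[bad[1]], sample_ids[bad[1]],
                 if (length(peptide_id) > 1) peptide_id[bad[1]] else peptide_id))
  neg <- which(v < 0)
  if (length(neg) > 0)
    stop(sprintf("negative intensity %s at sample '%s', peptide '%s'",
                 x[neg[1]], sample_ids[neg[1]],
                 if (length(peptide_id) > 1) peptide_id[neg[1]] else peptide_id))
  v
}

#' Write an intensity dataset as tab-separated text (wide layout)
#'
#' Inverse of [read_intensity_dataset()]: `write` then `read` reproduces the
#' matrix, labels and covariates exactly.
#'
#' @param x an `intensity_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_intensity_dataset <- function(x, path) {
  stopifnot(inherits(x, "intensity_dataset"))
  df <- data.frame(sample_id = rownames(x$intensities),
                   group = as.character(x$group),
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(x$etiology)) df$etiology <- ifelse(is.na(x$etiology), "", x$etiology)
  if (!is.null(x$covariates))
    for (cc in names(x$covariates)) df[[cc]] <- x$covariates[[cc]]
  mm <- as.data.frame(x$intensities, check.names = FALSE)
  # %.17g round-trips doubles exactly through read.delim
  for (j in names(mm)) mm[[j]] <- sprintf("%.17g", mm[[j]])
  utils::write.table(cbind(df, mm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
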