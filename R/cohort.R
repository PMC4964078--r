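#' Construct a clinical cohort table
#'
#' Validates and normalizes a per-sample clinical record: ER status, HER2
#' status, lymph-node (LN) status, and distant-metastasis-free survival
#' (DMFS) follow-up. Samples with missing ER, LN, or DMFS fields, or with
#' non-positive follow-up time, cannot enter an analysis-ready cohort; they
#' are removed and counted in the `"excluded"` attribute. Missing HER2 is
#' kept as `"unknown"` (it can be filled in later from expression calls).
#'
#' @param df data.frame with columns `sample_id`, `er_status`
#'   (positive/negative), `her2_status` (positive/negative/unknown),
#'   `ln_status` (positive/negative), `dmfs_time` (months, > 0) and
#'   `dmfs_event` (0/1).
#' @return A `cohort_table` (a validated data.frame).
#' @export
cohort_table <- function(df) {
  req <- c("sample_id", "er_status", "her2_status", "ln_status",
           "dmfs_time", "dmfs_event")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop_prognode("invalid_input",
                  paste("missing clinical columns:", paste(missing_cols, collapse = ", ")))
  df <- df[, req]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop_prognode("invalid_input", "duplicated sample ids in clinical table")
  norm <- function(x) tolower(trimws(as.character(x)))
  df$er_status <- norm(df$er_status)
  df$her2_status <- norm(df$her2_status)
  df$her2_status[is.na(df$her2_status) | df$her2_status %in% c("", "na")] <- "unknown"
  df$ln_status <- norm(df$ln_status)
  df$dmfs_time <- as.numeric(df$dmfs_time)
  df$dmfs_event <- as.integer(df$dmfs_event)

  bad_er <- is.na(df$er_status) | !df$er_status %in% c("positive", "negative")
  bad_ln <- is.na(df$ln_status) | !df$ln_status %in% c("positive", "negative")
  bad_fu <- is.na(df$dmfs_time) | df$dmfs_time <= 0 |
    is.na(df$dmfs_event) | !df$dmfs_event %in% c(0L, 1L)
  bad_her2 <- !df$her2_status %in% c("positive", "negative", "unknown")
  keep <- !(bad_er | bad_ln | bad_fu | bad_her2)
  excluded <- c(missing_er = sum(bad_er), missing_ln = sum(bad_ln & !bad_er),
                missing_dmfs = sum(bad_fu & !bad_er & !bad_ln),
                bad_her2 = sum(bad_her2 & !bad_er & !bad_ln & !bad_fu))
  out <- df[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    stop_prognode("empty_result", "no valid samples remain in the clinical table")
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "excluded") <- excluded
  out
}

#' Read a clinical annotation TSV
#'
#' Expects columns `sample_id`, `er_status`, `her2_status`, `ln_status`,
#' `dmfs_time_months`, `dmfs_event`.
#'
#' @param path TSV file path.
#' @return A [cohort_table()].
#' @export
read_clinical <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"")
  if ("dmfs_time_months" %in% names(df) && !"dmfs_time" %in% names(df))
    names(df)[names(df) == "dmfs_time_months"] <- "dmfs_time"
  cohort_table(df)
}

#' Write a cohort table as TSV
#' @param cohort a `cohort_table`.
#' @param path output path.
#' @export
write_clinical <- function(cohort, path) {
  df <- as.data.frame(cohort)
  names(df)[names(df) == "dmfs_time"] <- "dmfs_time_months"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align an expression matrix and a cohort table
#'
#' Restricts both objects to their shared samples, in the cohort's order.
#'
#' @param x an `expr_matrix`.
#' @param cohort a `cohort_table`.
#' @return list with elements `expression` and `cohort`.
#' @export
align_cohort <- function(x, cohort) {
  shared <- intersect(cohort$sample_id, sample_ids(x))
  if (length(shared) == 0L)
    stop_prognode("invalid_input", "no shared samples between expression and clinical data")
  cohort2 <- cohort[match(shared, cohort$sample_id), , drop = FALSE]
  rownames(cohort2) <- NULL
  class(cohort2) <- c("cohort_table", "data.frame")
  x2 <- expression_matrix(x$values[, shared, drop = FALSE], scale = x$scale)
  list(expression = x2, cohort = cohort2)
}

# Two-component Gaussian mixture overexpression call for one probe.
# Returns logical per sample. A forced two-component fit on unimodal data
# yields two overlapping components; the call is only trusted when the
# components are genuinely separated (Ashman's D =
# |mu1 - mu2| / sqrt((s1^2 + s2^2) / 2) >= 2, the usual bimodality bar),
# otherwise it falls back to a mean + 2*SD outlier threshold.
#' @importFrom mclust Mclust mclustBIC
call_overexpressed <- function(x) {
  fit <- tryCatch(
    mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL
  )
  if (!is.null(fit) && length(fit$parameters$mean) == 2L) {
    mu <- fit$parameters$mean
    varc <- fit$parameters$variance$sigmasq
    if (length(varc) == 1L) varc <- rep(varc, 2L)
    ashman_d <- abs(diff(mu)) / sqrt(mean(varc))
    if (ashman_d >= 2) {
      upper <- which.max(mu)
      return(fit$z[, upper] > 0.5)
    }
  }
  # degenerate or failed mixture: conservative outlier threshold
  x > mean(x) + 2 * stats::sd(x)
}

#' Call HER2 overexpression from expression probes
#'
#' A sample is called HER2-positive when *any* of the named probes is
#' overexpressed ("either probe" OR semantics). Per probe, overexpression is
#' a two-component Gaussian mixture call (positive when posterior membership
#' in the upper-mean component exceeds 0.5); if the fitted components are
#' degenerate (means closer than 0.5 x pooled SD) a mean + 2 SD threshold is
#' used instead.
#'
#' @param x an `expr_matrix` on the log2 scale.
#' @param her2_probe_ids probe/feature ids to use (typically the two HER2
#'   probes of the array).
#' @return character vector (`"positive"`/`"negative"`) named by sample id.
#' @export
classify_her2 <- function(x, her2_probe_ids) {
  if (x$scale != "log2")
    stop_prognode("invalid_input", "classify_her2 expects log2-scale intensities")
  present <- intersect(her2_probe_ids, gene_ids(x))
  if (length(present) == 0L)
    stop_prognode("missing_feature",
                  paste("none of the HER2 probes present:",
                        paste(her2_probe_ids, collapse = ", ")))
  calls <- vapply(present, function(p) call_overexpressed(x$values[p, ]),
                  logical(ncol(x$values)))
  pos <- apply(calls, 1L, any)
  stats::setNames(ifelse(pos, "positive", "negative"), sample_ids(x))
}

#' Filter to the ER+/HER2- analysis cohort
#'
#' Retains samples with `er_status == "positive"` and
#' `her2_status != "positive"`; expression values are untouched, only
#' membership changes. Removal counts per criterion (ER first, then HER2)
#' are recorded in the `"removed"` attribute.
#'
#' @param x an `expr_matrix` aligned to `cohort`.
#' @param cohort a `cohort_table` whose sample ids match `x` exactly.
#' @return list with filtered `expression` and `cohort`.
#' @export
filter_cohort <- function(x, cohort) {
  if (!identical(sort(cohort$sample_id), sort(sample_ids(x))))
    stop_prognode("invalid_input", "expression and cohort sample ids are not aligned")
  er_fail <- cohort$er_status != "positive"
  her2_fail <- !er_fail & cohort$her2_status == "positive"
  keep <- !er_fail & !her2_fail
  if (!any(keep))
    stop_prognode("empty_result", "no samples remain after ER/HER2 filtering")
  cohort2 <- cohort[keep, , drop = FALSE]
  rownames(cohort2) <- NULL
  class(cohort2) <- c("cohort_table", "data.frame")
  x2 <- expression_matrix(x$values[, cohort2$sample_id, drop = FALSE], scale = x$scale)
  out <- list(expression = x2, cohort = cohort2)
  attr(out, "removed") <- c(er_negative = sum(er_fail), her2_positive = sum(her2_fail))
  out
}
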