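score_with <- function(x, signature) {
  switch(signature,
         oncotype = oncotype_rs(x),
         prosigna = prosigna_ror(x),
         ellen = directional_mean_index(x),
         stop_prognode("invalid_input", paste("unknown signature:", signature)))
}

fit_row <- function(fit) {
  data.frame(signature = fit$signature, stratum = fit$stratum,
             n = fit$n, n_events = fit$n_events,
             beta = fit$beta, hr = fit$hr,
             ci_lower = fit$ci_lower, ci_upper = fit$ci_upper,
             p = fit$p, concordance = fit$concordance,
             orientation = fit$orientation, stringsAsFactors = FALSE)
}

#' Evaluate a score per lymph-node stratum
#'
#' Cox fit + concordance within the LN-negative and LN-positive strata (and
#' optionally combined).
#'
#' @param score a `score_vector`.
#' @param cohort a `cohort_table`.
#' @param combined include the unstratified fit (default FALSE).
#' @return data.frame of fits, one row per stratum.
#' @export
evaluate_by_stratum <- function(score, cohort, combined = FALSE) {
  strata <- list("LN-" = cohort$ln_status == "negative",
                 "LN+" = cohort$ln_status == "positive")
  if (combined) strata <- c(strata, list(combined = rep(TRUE, nrow(cohort))))
  rows <- lapply(names(strata), function(lbl) {
    sub <- cohort[strata[[lbl]], , drop = FALSE]
    class(sub) <- c("cohort_table", "data.frame")
    fit_row(cox_fit(score, sub, stratum = lbl))
  })
  do.call(rbind, rows)
}

#' Run the full signature-comparison analysis
#'
#' Stages: load/align expression and clinical data, optional HER2 calling
#' from probes, ER+/HER2- filtering, Z-standardization, optional probe
#' collapse, scoring of the requested signatures, and per-LN-stratum Cox /
#' concordance evaluation. Inputs are never mutated; the report records
#' removal counts and seeds.
#'
#' @param expression an `expr_matrix` (log2) or path readable by
#'   [read_expression()].
#' @param clinical a `cohort_table` or TSV path readable by
#'   [read_clinical()].
#' @param signatures signatures to score (default all three bundled ones).
#' @param probe_map optional probe-to-gene map (data.frame or named vector)
#'   triggering [collapse_probes()].
#' @param her2_probe_ids optional probe ids for expression-based HER2 calls;
#'   calls overwrite `"unknown"` HER2 entries.
#' @param combined also report unstratified fits (default FALSE).
#' @return An `analysis_report`.
#' @export
run_analysis <- function(expression, clinical,
                         signatures = c("oncotype", "prosigna", "ellen"),
                         probe_map = NULL, her2_probe_ids = NULL,
                         combined = FALSE) {
  if (is.character(expression)) expression <- read_expression(expression)
  if (is.character(clinical)) clinical <- read_clinical(clinical)
  al <- align_cohort(expression, clinical)
  x <- al$expression; cohort <- al$cohort

  if (!is.null(her2_probe_ids)) {
    calls <- classify_her2(x, her2_probe_ids)
    unk <- cohort$her2_status == "unknown"
    cohort$her2_status[unk] <- calls[cohort$sample_id[unk]]
  }
  filt <- filter_cohort(x, cohort)
  removed <- attr(filt, "removed")
  x <- z_standardize(filt$expression)
  dropped <- attr(x, "dropped") %||% character(0)
  cohort <- filt$cohort
  if (!is.null(probe_map)) x <- collapse_probes(x, probe_map)

  scores <- lapply(stats::setNames(signatures, signatures),
                   function(s) score_with(x, s))
  fits <- do.call(rbind, lapply(scores, function(s)
    evaluate_by_stratum(s, cohort, combined = combined)))
  rownames(fits) <- NULL

  onc <- load_builtin("oncotype"); pam <- load_builtin("pam50")
  ell <- load_builtin("ellen")
  pc <- pathway_counts(load_builtin("ellen_pathways"))
  structure(list(
    cohort_summary = list(
      n = nrow(cohort),
      n_ln_positive = sum(cohort$ln_status == "positive"),
      n_events = sum(cohort$dmfs_event),
      removed = as.list(removed),
      dropped_zero_variance = length(dropped)
    ),
    fits = fits,
    scores = scores,
    overlaps = list(
      oncotype_pam50 = signature_overlap(onc, pam),
      ellen_oncotype = signature_overlap(ell, onc),
      ellen_pam50 = signature_overlap(ell, pam)
    ),
    pathway_table = pc,
    metadata = list(signatures = signatures,
                    timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cs <- x$cohort_summary
  cat(sprintf("analysis report: n=%d (%d LN+), %d events\n",
              cs$n, cs$n_ln_positive, cs$n_events))
  df <- x$fits
  cat(sprintf("  %-10s %-9s  p=%-10.3g C=%.3f HR/SD=%.3f\n",
              df$signature, df$stratum, df$p, df$concordance, df$hr), sep = "")
  invisible(x)
}

#' Write an analysis report to disk
#'
#' JSON payload (without volatile timestamp) plus human-readable TSV tables.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  payload <- list(cohort_summary = report$cohort_summary,
                  fits = report$fits,
                  overlaps = report$overlaps,
                  pathway_table = report$pathway_table$by_pathway,
                  unique_genes = as.list(report$pathway_table$unique_genes))
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(report$fits, file.path(dir, "fits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$pathway_table$by_pathway,
                     file.path(dir, "pathways.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_scores(report$scores, file.path(dir, "scores.tsv"))
  invisible(dir)
}

#' Cross-cohort discovery and validation
#'
#' Mirrors the study's transfer design: discover a directional signature on
#' a training cohort (both LN strata pooled), then score and evaluate it per
#' LN stratum on an independent test cohort.
#'
#' @param train,test `synthetic_cohort` objects, or lists with `expression`
#'   (log2 `expr_matrix`) and `clinical` (`cohort_table`).
#' @param seed seed for fold assignment in CV.
#' @param k CV folds.
#' @return list: `signature`, `cv`, `model`, `fits` (test-cohort per-stratum
#'   evaluation), `test_score`.
#' @export
run_discovery <- function(train, test, seed = 1, k = 10) {
  ztr <- z_standardize(train$expression)
  disc <- discover_signature(ztr, train$clinical, seed = seed, k = k)
  zte <- z_standardize(test$expression)
  sc <- directional_mean_index(zte, disc$signature)
  fits <- evaluate_by_stratum(sc, test$clinical, combined = TRUE)
  list(signature = disc$signature, cv = disc$cv, model = disc$model,
       fits = fits, test_score = sc)
}
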