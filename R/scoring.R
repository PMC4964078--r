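#' Construct a per-sample score vector
#'
#' @param x named numeric vector (names = sample ids).
#' @param signature signature name.
#' @param orientation `"higher_is_worse"` (risk scores) or
#'   `"higher_is_better"` (protective indices).
#' @return A `score_vector`.
#' @export
score_vector <- function(x, signature,
                         orientation = c("higher_is_worse", "higher_is_better")) {
  orientation <- match.arg(orientation)
  if (is.null(names(x)))
    stop_prognode("invalid_input", "scores must be named by sample id")
  structure(as.numeric(x), names = names(x), signature = signature,
            orientation = orientation, class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("score '%s' (%s): n=%d, median=%.3f\n",
              attr(x, "signature"), attr(x, "orientation"), length(x),
              stats::median(unclass(x))))
  invisible(x)
}

score_orientation <- function(x) attr(x, "orientation") %||% "higher_is_worse"

#' Write score vectors as TSV
#' @param scores a `score_vector` or list of them.
#' @param path output path.
#' @export
write_scores <- function(scores, path) {
  if (inherits(scores, "score_vector")) scores <- list(scores)
  df <- do.call(rbind, lapply(scores, function(s) {
    data.frame(sample_id = names(s), score = as.numeric(s),
               signature = attr(s, "signature"),
               orientation = attr(s, "orientation"),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Fetch rows for the requested canonical symbols from a gene-keyed Z matrix,
# aborting (not renormalizing) when genes are absent.
fetch_gene_rows <- function(x, symbols, context) {
  if (x$scale != "zscore")
    stop_prognode("invalid_input", paste(context, "expects a Z-standardized matrix"))
  rows <- canonical_symbols(gene_ids(x))
  idx <- match(symbols, rows)
  if (anyNA(idx))
    stop_prognode("missing_feature",
                  paste0(context, ": missing gene(s): ",
                         paste(symbols[is.na(idx)], collapse = ", ")))
  m <- x$values[idx, , drop = FALSE]
  rownames(m) <- symbols
  m
}

#' Recurrence-score style weighted-group index
#'
#' Per sample, computes each functional group's weighted mean of member gene
#' Z values and combines the group scores linearly with the signature's
#' group coefficients. The result is the unscaled, Z-based analogue of the
#' commercial recurrence score (no 0-100 rescale, no group floors,
#' housekeeping normalization not applicable on RMA-style input); scores are
#' roughly centred on zero. Higher = worse prognosis.
#'
#' @param x gene-keyed Z-scaled `expr_matrix` containing all signature genes.
#' @param sig the weighted-group signature (default the bundled
#'   `"oncotype"` fixture).
#' @return A `score_vector` with orientation `higher_is_worse`.
#' @export
oncotype_rs <- function(x, sig = load_builtin("oncotype")) {
  if (is.null(sig$group_coefficients))
    stop_prognode("invalid_input", "signature carries no group coefficients")
  m <- fetch_gene_rows(x, sig$genes$symbol, "oncotype_rs")
  groups <- split(seq_len(nrow(sig$genes)), sig$genes$group)
  rs <- rep(0, ncol(m))
  for (g in names(groups)) {
    idx <- groups[[g]]
    w <- sig$genes$weight[idx]
    group_score <- crossprod(m[idx, , drop = FALSE], w)[, 1L]
    rs <- rs + sig$group_coefficients[[g]] * group_score
  }
  score_vector(stats::setNames(rs, sample_ids(x)), "oncotype", "higher_is_worse")
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties).
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop_prognode("invalid_input", "vectors differ in length")
  if (length(x) < 3L)
    stop_prognode("invalid_input", "need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_prognode("undefined_correlation", "correlation undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Intrinsic-subtype correlation risk-of-recurrence score
#'
#' Per sample, the Spearman correlation of the sample's gene profile to each
#' subtype centroid over the shared genes, combined linearly with the fixed
#' ROR coefficients (the correlation-only, "ROR-S"-like variant without a
#' proliferation or tumour-size term). Rank-based, so invariant to monotone
#' per-sample transforms. Higher = worse prognosis.
#'
#' @param x gene-keyed Z-scaled `expr_matrix`.
#' @param centroids a `subtype_centroids` object (default the bundled
#'   `"pam50"` fixture).
#' @param gene_subset optional character vector restricting scoring to these
#'   genes; `NULL` uses all centroid genes not on the fixture's exclusion
#'   list (mirroring the restricted probe set of array platforms).
#' @return A `score_vector` with orientation `higher_is_worse`.
#' @export
prosigna_ror <- function(x, centroids = load_builtin("pam50"), gene_subset = NULL) {
  genes <- rownames(centroids$centroids)
  if (is.null(gene_subset)) {
    genes <- setdiff(genes, centroids$excluded_genes)
  } else {
    genes <- intersect(genes, canonical_symbols(gene_subset))
  }
  rows <- canonical_symbols(gene_ids(x))
  genes <- genes[genes %in% rows]
  if (length(genes) < 10L)
    stop_prognode("missing_feature",
                  "fewer than 10 centroid genes present in the matrix")
  m <- x$values[match(genes, rows), , drop = FALSE]
  cen <- centroids$centroids[genes, names(centroids$ror_coefficients), drop = FALSE]
  coefs <- centroids$ror_coefficients
  ror <- apply(m, 2L, function(sample_vec) {
    rho <- vapply(colnames(cen),
                  function(k) spearman_rho(sample_vec, cen[, k]), numeric(1))
    sum(coefs * rho[names(coefs)])
  })
  score_vector(stats::setNames(ror, sample_ids(x)), "prosigna", "higher_is_worse")
}

#' Directional mean-Z prognostic index
#'
#' Mean Z over good-outcome genes minus mean Z over poor-outcome genes, so
#' the index correlates positively with survival (higher = better
#' prognosis).
#'
#' @param x gene-keyed Z-scaled `expr_matrix`.
#' @param sig a `gene_signature` with `good`/`poor` directions (default the
#'   bundled `"ellen"` fixture).
#' @return A `score_vector` with orientation `higher_is_better`.
#' @export
directional_mean_index <- function(x, sig = load_builtin("ellen")) {
  if (x$scale != "zscore")
    stop_prognode("invalid_input", "directional_mean_index expects a Z-standardized matrix")
  rows <- canonical_symbols(gene_ids(x))
  # a direction the signature declares must be represented in the matrix;
  # a direction the signature does not carry contributes a zero mean
  # (the empty-average convention, so one-sided discovered signatures score)
  side_mean <- function(direction) {
    declared <- sig$genes$symbol[sig$genes$direction == direction]
    if (length(declared) == 0L) return(0)
    present <- declared[declared %in% rows]
    if (length(present) == 0L)
      stop_prognode("missing_feature",
                    sprintf("no %s-direction signature gene present in the matrix",
                            direction))
    colMeans(x$values[match(present, rows), , drop = FALSE])
  }
  if (all(sig$genes$direction == "none"))
    stop_prognode("invalid_input", "signature carries no good/poor directions")
  idx <- side_mean("good") - side_mean("poor")
  score_vector(stats::setNames(idx, sample_ids(x)), sig$name, "higher_is_better")
}
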