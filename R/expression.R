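#' Construct an expression matrix
#'
#' Container for a genes/probes-by-samples expression matrix together with a
#' value-scale flag. On the `"log2"` scale values are RMA-like log2
#' intensities; on the `"zscore"` scale every row has been standardized to
#' mean 0 and unit sample standard deviation across samples (see
#' [z_standardize()]).
#'
#' @param values numeric matrix, rows = genes or probes (rownames required),
#'   columns = samples (unique colnames required).
#' @param scale value scale, `"log2"` or `"zscore"`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `scale`.
#' @export
expression_matrix <- function(values, scale = c("log2", "zscore")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop_prognode("invalid_input", "`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_prognode("invalid_input", "`values` must have rownames (features) and colnames (samples)")
  if (anyDuplicated(colnames(values)))
    stop_prognode("invalid_input", "duplicated sample ids in expression matrix")
  structure(list(values = values, scale = scale), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d features x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

as_expr_values <- function(x) {
  if (inherits(x, "expr_matrix")) x$values else x
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row of sample ids and a first column of feature ids;
#' the delimiter is inferred from the file extension (`.csv` = comma,
#' otherwise tab).
#'
#' @param path file path.
#' @param scale value scale of the stored numbers (default `"log2"`).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, scale = "log2") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          quote = "\"", comment.char = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  expression_matrix(m, scale = scale)
}

#' Write an expression matrix as TSV
#'
#' @param x an `expr_matrix`.
#' @param path output file path.
#' @param id_column name of the feature-id column (default `"feature_id"`).
#' @export
write_expression <- function(x, path, id_column = "feature_id") {
  v <- as_expr_values(x)
  df <- data.frame(rownames(v), v, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a GEO series-matrix file
#'
#' Reads the expression block between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` of a GEO series-matrix text file. Quoted
#' identifiers are unquoted; values are returned on the stated scale.
#'
#' @param path path to a series-matrix text file.
#' @param scale value scale flag to attach (default `"log2"`).
#' @return An [expression_matrix()].
#' @export
read_geo_series_matrix <- function(path, scale = "log2") {
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop_prognode("invalid_input", "no series-matrix table block found")
  block <- lines[(beg + 1L):(end - 1L)]
  con <- textConnection(block)
  on.exit(close(con))
  df <- utils::read.table(con, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "\"", comment.char = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gsub("^\"|\"$", "", as.character(df[[1]]))
  expression_matrix(m, scale = scale)
}

#' Z-standardize expression rows
#'
#' Per feature, subtracts the across-sample mean and divides by the
#' across-sample standard deviation (sample SD, `n - 1` denominator),
#' mimicking assay-style scoring on microarray intensities. Zero-variance
#' rows cannot be standardized and are dropped; their ids are recorded in
#' the `"dropped"` attribute.
#'
#' @param x an `expr_matrix` with at least 2 samples.
#' @return A Z-scaled `expr_matrix`; attribute `"dropped"` lists removed
#'   zero-variance feature ids.
#' @export
z_standardize <- function(x) {
  v <- as_expr_values(x)
  if (ncol(v) < 2L)
    stop_prognode("invalid_input", "Z-standardization needs at least 2 samples")
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  keep <- sdv > 0 & is.finite(sdv)
  if (!any(keep))
    stop_prognode("empty_result", "all rows are constant; nothing to standardize")
  z <- (v[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  out <- expression_matrix(z, scale = "zscore")
  attr(out, "dropped") <- rownames(v)[!keep]
  out
}

#' Collapse probes to gene symbols
#'
#' Averages the Z rows of all probes mapped to the same gene. Genes in the
#' map without any probe in the matrix are absent from the result and listed
#' in the `"missing_genes"` attribute.
#'
#' @param x a Z-scaled `expr_matrix` keyed by probe id.
#' @param probe_to_gene named character vector (`names` = probe ids, values =
#'   gene symbols) or a data.frame with columns `probe_id` and `gene`.
#' @return A gene-keyed Z-scaled `expr_matrix`.
#' @export
collapse_probes <- function(x, probe_to_gene) {
  if (is.data.frame(probe_to_gene)) {
    map <- stats::setNames(as.character(probe_to_gene$gene),
                           as.character(probe_to_gene$probe_id))
  } else map <- probe_to_gene
  if (length(map) == 0L)
    stop_prognode("invalid_input", "empty probe-to-gene map")
  if (x$scale != "zscore")
    stop_prognode("invalid_input", "collapse_probes expects a Z-standardized matrix")
  v <- x$values
  present <- intersect(names(map), rownames(v))
  genes <- unique(unname(map))
  rows <- lapply(genes, function(g) {
    probes <- intersect(names(map)[map == g], present)
    if (length(probes) == 0L) return(NULL)
    colMeans(v[probes, , drop = FALSE])
  })
  found <- !vapply(rows, is.null, logical(1))
  if (!any(found))
    stop_prognode("empty_result", "no mapped probe present in the matrix")
  m <- do.call(rbind, rows[found])
  rownames(m) <- genes[found]
  out <- expression_matrix(m, scale = "zscore")
  attr(out, "missing_genes") <- genes[!found]
  out
}
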