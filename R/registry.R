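#' Construct a gene signature
#'
#' @param name signature name.
#' @param genes data.frame with column `symbol` and optional columns
#'   `direction` (`good`/`poor`/`none`), `group`, `weight`,
#'   `symbol_published`.
#' @return A `gene_signature` object.
#' @export
gene_signature <- function(name, genes) {
  if (!"symbol" %in% names(genes))
    stop_prognode("invalid_input", "signature genes need a `symbol` column")
  genes$symbol <- toupper(as.character(genes$symbol))
  if (anyDuplicated(genes$symbol))
    stop_prognode("corrupt_fixture",
                  paste("duplicated symbols in signature", name))
  if (is.null(genes$direction)) genes$direction <- "none"
  if (!all(genes$direction %in% c("good", "poor", "none")))
    stop_prognode("corrupt_fixture", "direction must be good/poor/none")
  structure(list(name = name, genes = genes), class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  dirs <- table(factor(x$genes$direction, c("good", "poor", "none")))
  cat(sprintf("gene signature '%s': %d genes (%d good, %d poor)\n",
              x$name, nrow(x$genes), dirs[["good"]], dirs[["poor"]]))
  invisible(x)
}

load_aliases <- function() {
  df <- utils::read.table(extdata_path("gene_aliases.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(df$symbol, toupper(df$alias))
}

# Map published symbols to canonical HGNC-style symbols via the bundled
# alias table; unknown symbols pass through (upper-cased).
canonical_symbols <- function(symbols) {
  al <- load_aliases()
  up <- toupper(symbols)
  hit <- up %in% names(al)
  up[hit] <- unname(al[up[hit]])
  up
}

symbols_of <- function(x) {
  if (inherits(x, "gene_signature")) return(x$genes$symbol)
  if (inherits(x, "subtype_centroids")) return(rownames(x$centroids))
  if (is.character(x)) return(toupper(x))
  stop_prognode("invalid_input", "cannot extract gene symbols from this object")
}

load_oncotype <- function() {
  df <- utils::read.table(extdata_path("oncotype_signature.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  coefs <- jsonlite::read_json(extdata_path("oncotype_group_coefficients.json"),
                               simplifyVector = TRUE)
  genes <- data.frame(symbol = canonical_symbols(df$symbol),
                      symbol_published = df$symbol,
                      group = df$group, weight = df$weight,
                      direction = "none", stringsAsFactors = FALSE)
  if (!setequal(unique(genes$group), names(coefs)))
    stop_prognode("corrupt_fixture", "group coefficients do not match gene groups")
  # each gene in exactly one group
  if (anyDuplicated(genes$symbol))
    stop_prognode("corrupt_fixture", "a gene appears in more than one group")
  sig <- gene_signature("oncotype", genes)
  sig$group_coefficients <- unlist(coefs)
  sig
}

load_ellen <- function() {
  df <- utils::read.table(extdata_path("ellen_signature.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  if (!all(df$direction %in% c("good", "poor")))
    stop_prognode("corrupt_fixture", "every Ellen gene must be labeled good or poor")
  gene_signature("ellen", data.frame(symbol = canonical_symbols(df$symbol),
                                     symbol_published = df$symbol,
                                     direction = df$direction,
                                     stringsAsFactors = FALSE))
}

load_pam50 <- function() {
  cen <- utils::read.table(extdata_path("pam50_centroids_synthetic.tsv"),
                           header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(extdata_path("pam50_ror_coefficients.json"),
                              simplifyVector = TRUE)
  m <- as.matrix(cen[, -1, drop = FALSE])
  rownames(m) <- canonical_symbols(cen$symbol)
  if (anyDuplicated(rownames(m)))
    stop_prognode("corrupt_fixture", "duplicated genes in centroid matrix")
  coefs <- unlist(meta$coefficients)
  if (!all(names(coefs) %in% colnames(m)))
    stop_prognode("corrupt_fixture", "coefficient subtype absent from centroid matrix")
  structure(list(
    genes = rownames(m),
    centroids = m,
    ror_coefficients = coefs,
    excluded_genes = canonical_symbols(meta$excluded_genes),
    symbols_published = cen$symbol,
    version = meta$version
  ), class = "subtype_centroids")
}

#' @export
print.subtype_centroids <- function(x, ...) {
  cat(sprintf("subtype centroids: %d genes x %d subtypes; ROR coefficients on %s\n",
              nrow(x$centroids), ncol(x$centroids),
              paste(names(x$ror_coefficients), collapse = ", ")))
  invisible(x)
}

load_ellen_pathways <- function() {
  df <- utils::read.table(extdata_path("ellen_pathways.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  df$symbol <- toupper(df$symbol)
  sig <- load_ellen()
  if (!all(df$symbol %in% sig$genes$symbol))
    stop_prognode("corrupt_fixture",
                  "pathway annotation names a gene outside the Ellen signature")
  class(df) <- c("pathway_annotation", "data.frame")
  df
}

#' Load a bundled signature fixture
#'
#' Bundled constants: the 16-gene / 7-group weighted recurrence-score
#' signature (`"oncotype"`), the 50-gene intrinsic-subtype centroid matrix
#' with ROR combination coefficients (`"pam50"`; centroid *values* are
#' synthetic stand-ins, see the fixture file), the 58-gene directional
#' mean-Z signature (`"ellen"`), and its per-pathway annotation
#' (`"ellen_pathways"`). Published symbols are mapped to canonical symbols
#' through a bundled alias table at load time.
#'
#' @param name one of `"oncotype"`, `"pam50"`, `"ellen"`, `"ellen_pathways"`.
#' @return A `gene_signature`, `subtype_centroids`, or `pathway_annotation`.
#' @export
load_builtin <- function(name = c("oncotype", "pam50", "ellen", "ellen_pathways")) {
  name <- match.arg(name)
  switch(name,
         oncotype = load_oncotype(),
         pam50 = load_pam50(),
         ellen = load_ellen(),
         ellen_pathways = load_ellen_pathways())
}

#' Intersect two signatures' gene lists
#'
#' Case-normalized set intersection of canonical symbols; accepts
#' `gene_signature`, `subtype_centroids`, or plain character vectors.
#'
#' @param a,b signatures.
#' @return sorted character vector of shared symbols.
#' @export
signature_overlap <- function(a, b) {
  sort(intersect(symbols_of(a), symbols_of(b)))
}

#' Tabulate pathway annotation counts
#'
#' Counts annotation records per pathway and direction, and deduplicated
#' gene totals per direction (a gene annotated to several pathways counts
#' once in the unique totals).
#'
#' @param ann a `pathway_annotation`.
#' @return list with `by_pathway` (data.frame of `pathway`, `n_good`,
#'   `n_poor`, `n_total`) and `unique_genes` (named counts `good`, `poor`).
#' @export
pathway_counts <- function(ann) {
  if (!inherits(ann, "pathway_annotation"))
    stop_prognode("invalid_input", "expected a pathway_annotation")
  tab <- table(ann$pathway, factor(ann$direction, c("good", "poor")))
  by_pathway <- data.frame(pathway = rownames(tab),
                           n_good = as.integer(tab[, "good"]),
                           n_poor = as.integer(tab[, "poor"]),
                           stringsAsFactors = FALSE)
  by_pathway$n_total <- by_pathway$n_good + by_pathway$n_poor
  # keep the annotation file's pathway order
  by_pathway <- by_pathway[match(unique(ann$pathway), by_pathway$pathway), ]
  rownames(by_pathway) <- NULL
  uniq <- c(good = length(unique(ann$symbol[ann$direction == "good"])),
            poor = length(unique(ann$symbol[ann$direction == "poor"])))
  list(by_pathway = by_pathway, unique_genes = uniq)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member symbols.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop_prognode("invalid_input", "empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad))
    stop_prognode("invalid_input", "malformed GMT line (need name, description, >=1 gene)")
  stats::setNames(lapply(parts, function(p) unique(toupper(p[-(1:2)]))),
                  vapply(parts, `[[`, character(1), 1L))
}
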