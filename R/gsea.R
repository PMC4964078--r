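# Signal-to-noise metric per gene between two phenotype classes, with the
# usual GSEA floor on each class SD: s >= max(0.2 * |class mean|, 0.2).
signal_to_noise <- function(v, labels) {
  a <- labels == levels(labels)[1L]
  b <- !a
  ma <- rowMeans(v[, a, drop = FALSE]); mb <- rowMeans(v[, b, drop = FALSE])
  sa <- apply(v[, a, drop = FALSE], 1L, stats::sd)
  sb <- apply(v[, b, drop = FALSE], 1L, stats::sd)
  sa <- pmax(sa, pmax(0.2 * abs(ma), 0.2))
  sb <- pmax(sb, pmax(0.2 * abs(mb), 0.2))
  (ma - mb) / (sa + sb)
}

#' Rank genes by signal-to-noise between outcome classes
#'
#' Per gene, `(mu_A - mu_B) / (sigma_A + sigma_B)` with each class SD floored
#' at `max(0.2 * |class mean|, 0.2)` (standard GSEA practice); class A is the
#' first factor level. The list is ordered metric-descending with
#' deterministic tie-breaking by symbol.
#'
#' @param x `expr_matrix` or genes-by-samples matrix.
#' @param labels two-class factor, >= 3 samples per class.
#' @return A `ranked_list` data.frame with columns `symbol`, `metric`.
#' @export
rank_by_signal_to_noise <- function(x, labels) {
  v <- as_expr_values(x)
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    stop_prognode("invalid_input", "need exactly two classes")
  if (any(table(labels) < 3L))
    stop_prognode("invalid_input", "each class needs at least 3 samples")
  metric <- signal_to_noise(v, labels)
  ord <- order(-metric, rownames(v))
  out <- data.frame(symbol = rownames(v)[ord], metric = metric[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

# Core weighted Kolmogorov-Smirnov running sum. `metric` is ordered
# descending; `hit` marks set members. Returns list(es, running).
running_sum_es <- function(metric, hit, p = 1) {
  N <- length(metric)
  NH <- sum(hit)
  w <- abs(metric)^p
  inc <- numeric(N)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (N - NH)
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

#' Gene-set enrichment score over a ranked list
#'
#' Walks the ranked list accumulating `|metric|^p / sum_hits |metric|^p` at
#' set members and `-1 / (N - N_H)` at non-members; the enrichment score is
#' the signed maximum-magnitude deviation of the running sum from zero.
#'
#' @param ranked a `ranked_list` from [rank_by_signal_to_noise()].
#' @param gene_set character vector of member symbols.
#' @param p hit-weighting exponent (default 1; `p = 0` gives the classic
#'   unweighted Kolmogorov-Smirnov statistic).
#' @param name gene-set name for the result.
#' @return An `enrichment_result`: `es`, `running_sum`, `n_genes` (members
#'   present), `set_size`, `name`.
#' @export
enrichment_score <- function(ranked, gene_set, p = 1, name = "gene_set") {
  hit <- ranked$symbol %in% toupper(gene_set)
  if (!any(hit))
    stop_prognode("empty_overlap", "no gene-set member present in the ranked list")
  if (all(hit))
    stop_prognode("degenerate_set", "gene set covers the entire ranked list")
  rs <- running_sum_es(ranked$metric, hit, p = p)
  structure(list(name = name, es = rs$es, running_sum = rs$running,
                 n_genes = sum(hit), set_size = length(unique(toupper(gene_set)))),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment '%s': ES=%.3f (%d/%d members present)\n",
              x$name, x$es, x$n_genes, x$set_size))
  invisible(x)
}

#' Phenotype-permutation GSEA
#'
#' For each gene set: observed enrichment score on the signal-to-noise
#' ranking, then `n_perm` phenotype-label permutations re-ranking the list
#' each time. `NES = ES / mean(|permuted ES| of the same sign)`; the nominal
#' p-value is the fraction of same-sign permuted scores at least as extreme
#' as the observed one. Deterministic under `seed`.
#'
#' @param x `expr_matrix` or matrix, genes by samples.
#' @param labels two-class factor.
#' @param gene_sets named list of symbol vectors (e.g. from [read_gmt()]).
#' @param n_perm number of permutations (>= 10).
#' @param seed integer seed.
#' @param p hit-weighting exponent.
#' @return A `gsea_result`: data.frame with `name`, `es`, `nes`, `p_value`,
#'   `n_genes`; attributes `n_perm`, `seed`.
#' @export
gsea_permutation <- function(x, labels, gene_sets, n_perm = 1000, seed = 1, p = 1) {
  if (n_perm < 10L)
    stop_prognode("invalid_input", "need at least 10 permutations")
  if (is.null(names(gene_sets)))
    stop_prognode("invalid_input", "gene_sets must be a named list")
  v <- as_expr_values(x)
  labels <- factor(labels)
  ranked <- rank_by_signal_to_noise(v, labels)
  hits <- lapply(gene_sets, function(gs) ranked$symbol %in% toupper(gs))
  usable <- vapply(hits, function(h) any(h) && !all(h), logical(1))
  obs <- rep(NA_real_, length(gene_sets))
  obs[usable] <- vapply(which(usable), function(i)
    running_sum_es(ranked$metric, hits[[i]], p = p)$es, numeric(1))

  perm_es <- with_seed(seed, {
    out <- matrix(NA_real_, n_perm, length(gene_sets))
    for (b in seq_len(n_perm)) {
      pl <- sample(labels)
      pr <- rank_by_signal_to_noise(v, pl)
      ph <- lapply(gene_sets, function(gs) pr$symbol %in% toupper(gs))
      out[b, usable] <- vapply(which(usable), function(i)
        running_sum_es(pr$metric, ph[[i]], p = p)$es, numeric(1))
    }
    out
  })

  nes <- p_val <- rep(NA_real_, length(gene_sets))
  for (i in which(usable)) {
    same <- perm_es[, i] * sign(obs[i]) > 0
    if (any(same)) {
      nes[i] <- obs[i] / mean(abs(perm_es[same, i]))
      p_val[i] <- mean(abs(perm_es[same, i]) >= abs(obs[i]))
    }
  }
  res <- data.frame(name = names(gene_sets), es = obs, nes = nes,
                    p_value = p_val,
                    n_genes = vapply(hits, sum, integer(1)),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("gsea_result", "data.frame")
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- seed
  res
}

#' Per-stratum GSEA on outcome classes
#'
#' Runs [gsea_permutation()] separately within the LN-negative and
#' LN-positive strata, using 10-year outcome classes
#' (see [outcome_classes()]) as the phenotype.
#'
#' @param x gene-keyed `expr_matrix` aligned to `cohort`.
#' @param cohort a `cohort_table`.
#' @param gene_sets named list of symbol vectors.
#' @param horizon class horizon in months.
#' @param ... passed to [gsea_permutation()].
#' @return named list of `gsea_result` (`ln_neg`, `ln_pos`).
#' @export
gsea_by_stratum <- function(x, cohort, gene_sets, horizon = 120, ...) {
  cls <- outcome_classes(cohort, horizon)
  v <- as_expr_values(x)[, cohort$sample_id, drop = FALSE]
  strata <- c(ln_neg = "negative", ln_pos = "positive")
  lapply(strata, function(st) {
    sel <- cohort$ln_status == st & !is.na(cls)
    gsea_permutation(v[, sel, drop = FALSE], droplevels(cls[sel]),
                     gene_sets, ...)
  })
}
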