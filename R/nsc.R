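#' Train a nearest-shrunken-centroid (PAM-style) classifier
#'
#' Standard shrunken-centroid equations: per gene g and class k, the
#' standardized centroid distance is
#' `d_kg = (xbar_kg - xbar_g) / (m_k * (s_g + s0))`, with pooled within-class
#' SD `s_g`, fudge constant `s0 = median(s_g)`, and
#' `m_k = sqrt(1/n_k - 1/n)`. Distances are soft-thresholded by `delta`
#' (`d'_kg = sign(d) * max(|d| - delta, 0)`) and shrunken class centroids are
#' `xbar_g + m_k * (s_g + s0) * d'_kg`. A gene survives when any class has
#' `|d'_kg| > 0`. Class priors are the observed class proportions.
#'
#' @param x `expr_matrix` (Z scale) or plain genes-by-samples matrix.
#' @param labels class labels, one per sample (coerced to factor; the factor
#'   level order fixes prediction tie-breaking).
#' @param delta shrinkage threshold, >= 0.
#' @return An `nsc_model`.
#' @export
nsc_train <- function(x, labels, delta = 0) {
  v <- as_expr_values(x)
  labels <- factor(labels)
  if (nlevels(labels) < 2L)
    stop_prognode("invalid_input", "labels contain a single class")
  if (length(labels) != ncol(v))
    stop_prognode("invalid_input", "one label per sample required")
  nk <- table(labels)
  if (any(nk < 2L))
    stop_prognode("invalid_input", "every class needs at least 2 samples")
  if (delta < 0)
    stop_prognode("invalid_input", "delta must be >= 0")
  n <- ncol(v)
  K <- nlevels(labels)
  overall <- rowMeans(v)
  class_centroids <- vapply(levels(labels), function(k)
    rowMeans(v[, labels == k, drop = FALSE]), numeric(nrow(v)))
  # pooled within-class variance, n - K denominator
  ss <- matrix(0, nrow(v), K)
  for (j in seq_len(K)) {
    sub <- v[, labels == levels(labels)[j], drop = FALSE]
    ss[, j] <- rowSums((sub - class_centroids[, j])^2)
  }
  s <- sqrt(rowSums(ss) / (n - K))
  names(s) <- rownames(v)
  s0 <- stats::median(s)
  mk <- sqrt(1 / as.numeric(nk) - 1 / n)
  names(mk) <- levels(labels)
  denom <- outer(s + s0, mk)
  d <- (class_centroids - overall) / denom
  d_shrunk <- sign(d) * pmax(abs(d) - delta, 0)
  shrunken_centroids <- overall + denom * d_shrunk
  dimnames(shrunken_centroids) <- dimnames(class_centroids)
  surviving <- rownames(v)[rowSums(abs(d_shrunk) > 0) > 0L]
  structure(list(
    delta = delta,
    classes = levels(labels),
    priors = as.numeric(nk) / n,
    overall_centroid = overall,
    class_centroids = class_centroids,
    shrunken_centroids = shrunken_centroids,
    s = s, s0 = s0, mk = mk,
    d = d, d_shrunk = d_shrunk,
    surviving = surviving,
    gene_ids = rownames(v),
    n = n
  ), class = "nsc_model")
}

#' @export
print.nsc_model <- function(x, ...) {
  cat(sprintf("nearest-shrunken-centroid model: %d classes, delta=%.4g, %d/%d surviving genes\n",
              length(x$classes), x$delta, length(x$surviving), length(x$gene_ids)))
  invisible(x)
}

#' Predict classes from a shrunken-centroid model
#'
#' Discriminant score for class k:
#' `delta_k(x) = sum_g (x_g - xbar'_kg)^2 / (s_g + s0)^2 - 2 log pi_k`,
#' summed over surviving genes; the predicted class minimizes the score,
#' ties broken toward the class listed first. With zero surviving genes the
#' prior term alone decides (majority class).
#'
#' @param model an `nsc_model`.
#' @param x named numeric vector, genes-by-samples matrix, or `expr_matrix`;
#'   must cover the surviving genes.
#' @return list with `class` (character vector per sample) and `scores`
#'   (samples-by-classes discriminant matrix).
#' @export
nsc_predict <- function(model, x) {
  v <- as_expr_values(x)
  if (is.null(dim(v))) {
    if (is.null(names(v)))
      stop_prognode("invalid_input", "sample vector must be named by gene")
    v <- matrix(v, ncol = 1L, dimnames = list(names(v), "sample1"))
  }
  genes <- model$surviving
  if (length(genes)) {
    miss <- setdiff(genes, rownames(v))
    if (length(miss))
      stop_prognode("missing_feature",
                    paste("missing surviving gene(s):", paste(miss, collapse = ", ")))
  }
  K <- length(model$classes)
  scores <- matrix(0, ncol(v), K, dimnames = list(colnames(v), model$classes))
  for (j in seq_len(K)) {
    if (length(genes)) {
      cen <- model$shrunken_centroids[match(genes, model$gene_ids), j]
      sg <- (model$s + model$s0)[match(genes, model$gene_ids)]
      diff2 <- (v[genes, , drop = FALSE] - cen)^2 / sg^2
      scores[, j] <- colSums(diff2)
    }
    scores[, j] <- scores[, j] - 2 * log(model$priors[j])
  }
  cls <- model$classes[apply(scores, 1L, which.min)]
  list(class = stats::setNames(cls, colnames(v)), scores = scores)
}

#' @export
predict.nsc_model <- function(object, newdata, ...) nsc_predict(object, newdata)

make_stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validate the shrinkage threshold
#'
#' Stratified k-fold cross-validation of held-out misclassification error
#' over a grid of shrinkage thresholds. The chosen threshold attains the
#' minimal CV error; ties are broken toward the *larger* threshold (fewer
#' genes). Fold assignment is fixed by `seed`.
#'
#' @param x `expr_matrix` or matrix, genes by samples.
#' @param labels class labels.
#' @param delta_grid thresholds to evaluate; default 30 evenly spaced values
#'   from 0 to the full-data `max |d_kg|`.
#' @param k number of folds (default 10).
#' @param seed integer seed for fold assignment.
#' @return An `nsc_cv` object: `delta_grid`, `errors`, `best_delta`, `folds`,
#'   `seed`.
#' @export
nsc_cv <- function(x, labels, delta_grid = NULL, k = 10, seed = 1) {
  v <- as_expr_values(x)
  labels <- factor(labels)
  if (nlevels(labels) < 2L)
    stop_prognode("invalid_input", "labels contain a single class")
  if (is.null(delta_grid)) {
    full <- nsc_train(v, labels, delta = 0)
    delta_grid <- seq(0, max(abs(full$d)), length.out = 30L)
  }
  if (length(delta_grid) == 0L)
    stop_prognode("invalid_input", "empty delta grid")
  if (any(table(labels) < 2L))
    stop_prognode("invalid_input", "degenerate stratification: a class has < 2 samples")
  k <- min(k, min(table(labels)))
  folds <- with_seed(seed, make_stratified_folds(labels, k))
  errs <- matrix(NA_real_, length(delta_grid), k)
  wrong <- matrix(0, length(delta_grid), k)
  nheld <- integer(k)
  for (f in seq_len(k)) {
    test <- folds == f
    if (nlevels(droplevels(labels[!test])) < 2L) next
    fit0 <- nsc_train(v[, !test, drop = FALSE], labels[!test], delta = 0)
    nheld[f] <- sum(test)
    for (gi in seq_along(delta_grid)) {
      fit <- shrink_model(fit0, delta_grid[gi])
      pred <- nsc_predict(fit, v[, test, drop = FALSE])$class
      wrong[gi, f] <- sum(pred != as.character(labels[test]))
    }
  }
  errors <- rowSums(wrong) / sum(nheld)
  best <- max(delta_grid[errors == min(errors)])
  structure(list(delta_grid = delta_grid, errors = errors, best_delta = best,
                 folds = folds, k = k, seed = seed), class = "nsc_cv")
}

# Re-threshold an already-trained delta=0 model (avoids recomputing
# centroids for every grid point).
shrink_model <- function(model, delta) {
  denom <- outer(model$s + model$s0, model$mk)
  d_shrunk <- sign(model$d) * pmax(abs(model$d) - delta, 0)
  model$delta <- delta
  model$d_shrunk <- d_shrunk
  model$shrunken_centroids <- model$overall_centroid + denom * d_shrunk
  dimnames(model$shrunken_centroids) <- dimnames(model$class_centroids)
  model$surviving <- model$gene_ids[rowSums(abs(d_shrunk) > 0) > 0L]
  model
}

#' @export
print.nsc_cv <- function(x, ...) {
  cat(sprintf("NSC %d-fold CV: best delta=%.4g (error %.3f) over %d grid points\n",
              x$k, x$best_delta, min(x$errors), length(x$delta_grid)))
  invisible(x)
}

#' Derive a directional signature from a trained model
#'
#' Each surviving gene is labeled `poor` when its event-class shrunken
#' centroid exceeds the overall centroid (elevated in metastasizing
#' tumours), otherwise `good`. The result feeds
#' [directional_mean_index()].
#'
#' @param model an `nsc_model`.
#' @param event_class the class label representing the event (distant
#'   metastasis).
#' @param name signature name for the result.
#' @return A `gene_signature`.
#' @export
derive_signature <- function(model, event_class, name = "discovered") {
  if (!event_class %in% model$classes)
    stop_prognode("invalid_input", paste("unknown event class:", event_class))
  if (length(model$surviving) == 0L)
    stop_prognode("empty_signature", "no surviving genes at this threshold")
  j <- match(event_class, model$classes)
  idx <- match(model$surviving, model$gene_ids)
  dir_val <- model$d_shrunk[idx, j]
  zero <- dir_val == 0
  dir_val[zero] <- model$d[idx[zero], j]
  gene_signature(name, data.frame(
    symbol = model$surviving,
    direction = ifelse(dir_val > 0, "poor", "good"),
    stringsAsFactors = FALSE
  ))
}

#' Build 10-year outcome classes from a cohort
#'
#' `event`: distant metastasis within the horizon. `event_free`: no event
#' and follow-up reaching the horizon (an event *after* the horizon also
#' counts as event-free at the horizon). Samples censored before the
#' horizon are unusable for two-class training and get `NA`.
#'
#' @param cohort a `cohort_table`.
#' @param horizon months (default 120 = 10-year DMFS).
#' @return factor (`event_free`, `event`) with `NA` for early-censored
#'   samples, named by sample id.
#' @export
outcome_classes <- function(cohort, horizon = 120) {
  cls <- rep(NA_character_, nrow(cohort))
  cls[cohort$dmfs_event == 1L & cohort$dmfs_time <= horizon] <- "event"
  cls[cohort$dmfs_time >= horizon &
        !(cohort$dmfs_event == 1L & cohort$dmfs_time <= horizon)] <- "event_free"
  factor(stats::setNames(cls, cohort$sample_id), levels = c("event_free", "event"))
}

#' Discover a directional signature on outcome classes
#'
#' Full discovery stage: 10-year DMFS outcome classes (early-censored
#' samples excluded), cross-validated shrinkage-threshold choice, training
#' at the chosen threshold, direction assignment.
#'
#' @param x gene-keyed Z-scaled `expr_matrix`.
#' @param cohort a `cohort_table` aligned to `x`.
#' @param horizon class horizon in months (default 120).
#' @param delta_grid,k,seed passed to [nsc_cv()].
#' @param name name for the derived signature.
#' @return list with `signature`, `model`, `cv`, and `classes` used.
#' @export
discover_signature <- function(x, cohort, horizon = 120, delta_grid = NULL,
                               k = 10, seed = 1, name = "discovered") {
  cls <- outcome_classes(cohort, horizon)
  usable <- !is.na(cls)
  if (sum(usable) < 4L)
    stop_prognode("invalid_input", "too few class-assignable samples for discovery")
  v <- as_expr_values(x)[, cohort$sample_id[usable], drop = FALSE]
  labels <- droplevels(cls[usable])
  cv <- nsc_cv(v, labels, delta_grid = delta_grid, k = k, seed = seed)
  model <- nsc_train(v, labels, delta = cv$best_delta)
  sig <- derive_signature(model, "event", name = name)
  list(signature = sig, model = model, cv = cv, classes = cls)
}
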