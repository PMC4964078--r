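align_score_cohort <- function(score, cohort) {
  if (!is.null(names(score))) {
    shared <- intersect(cohort$sample_id, names(score))
    if (length(shared) == 0L)
      stop_prognode("invalid_input", "score and cohort share no samples")
    cohort <- cohort[match(shared, cohort$sample_id), , drop = FALSE]
    s <- unclass(score)[shared]
    attributes(s) <- attributes(score)[c("signature", "orientation", "class")]
    names(s) <- shared
    list(score = s, cohort = cohort)
  } else {
    if (length(score) != nrow(cohort))
      stop_prognode("invalid_input", "unnamed score must match the cohort length")
    list(score = score, cohort = cohort)
  }
}

#' Harrell's concordance index for a censored outcome
#'
#' Over comparable pairs (the member with the earlier time has an event;
#' strictly earlier), the fraction where the risk-oriented score is higher
#' for the earlier event; tied scores count 0.5. Scores with orientation
#' `higher_is_better` are negated first, so C > 0.5 always means prognostic
#' in the claimed direction.
#'
#' @param score numeric vector or `score_vector`, aligned to `cohort` (by
#'   names when present).
#' @param cohort a `cohort_table`.
#' @return concordance in `[0, 1]`.
#' @export
concordance_index <- function(score, cohort) {
  al <- align_score_cohort(score, cohort)
  risk <- as.numeric(al$score)
  if (score_orientation(al$score) == "higher_is_better") risk <- -risk
  t <- al$cohort$dmfs_time
  e <- al$cohort$dmfs_event
  comparable <- outer(t, t, `<`) & (e == 1L)   # row i earlier with event
  n_comp <- sum(comparable)
  if (n_comp == 0L)
    stop_prognode("undefined_statistic", "no comparable pairs")
  rd <- outer(risk, risk, `-`)
  concordant <- sum(comparable & rd > 0) + 0.5 * sum(comparable & rd == 0)
  concordant / n_comp
}

#' Univariate Cox proportional-hazards fit for a signature score
#'
#' Standardizes the score to unit SD (so the hazard ratio is per SD of
#' score, comparable across signatures), then fits a single-covariate Cox
#' model on DMFS with Efron tie handling. Reports the Wald 95% CI and
#' p-value and attaches [concordance_index()] computed in the score's native
#' orientation.
#'
#' @param score numeric vector or `score_vector`.
#' @param cohort a `cohort_table`.
#' @param stratum optional label stored in the result (e.g. `"LN-"`).
#' @return A `survival_fit`: `beta`, `se`, `hr`, `ci_lower`, `ci_upper`,
#'   `p`, `concordance`, `n`, `n_events`, `stratum`, `signature`,
#'   `orientation`.
#' @export
cox_fit <- function(score, cohort, stratum = NA_character_) {
  al <- align_score_cohort(score, cohort)
  s <- as.numeric(al$score)
  co <- al$cohort
  if (sum(co$dmfs_event) < 2L)
    stop_prognode("invalid_input", "need at least 2 events for a Cox fit")
  if (stats::sd(s) == 0)
    stop_prognode("invalid_input", "score is constant")
  z <- (s - mean(s)) / stats::sd(s)
  fit <- tryCatch(
    survival::coxph(survival::Surv(co$dmfs_time, co$dmfs_event) ~ z,
                    ties = "efron",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w)
      stop_prognode("nonconvergence", paste("Cox fit did not converge:",
                                            conditionMessage(w))),
    error = function(e)
      stop_prognode("nonconvergence", conditionMessage(e))
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1L, 1L]))
  zq <- stats::qnorm(0.975)
  structure(list(
    beta = beta, se = se, hr = exp(beta),
    ci_lower = exp(beta - zq * se), ci_upper = exp(beta + zq * se),
    p = 2 * stats::pnorm(-abs(beta / se)),
    concordance = concordance_index(al$score, co),
    n = nrow(co), n_events = sum(co$dmfs_event),
    stratum = stratum,
    signature = attr(score, "signature") %||% "score",
    orientation = score_orientation(al$score)
  ), class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf(
    "%s%s: HR/SD %.3f (95%% CI %.3f-%.3f), p=%.3g, C=%.3f (n=%d, events=%d)\n",
    x$signature, if (is.na(x$stratum)) "" else paste0(" [", x$stratum, "]"),
    x$hr, x$ci_lower, x$ci_upper, x$p, x$concordance, x$n, x$n_events))
  invisible(x)
}

# Product-limit (Kaplan-Meier) estimate for one group.
km_curve <- function(time, event) {
  ut <- sort(unique(time[event == 1L]))
  n_risk <- vapply(ut, function(t0) sum(time >= t0), integer(1))
  n_event <- vapply(ut, function(t0) sum(time == t0 & event == 1L), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  list(time = ut, n_risk = n_risk, n_event = n_event, surv = surv)
}

#' Median-split Kaplan-Meier comparison
#'
#' Splits samples at the median score (ties to the high group), computes
#' product-limit survival curves per group, and the two-group log-rank
#' test.
#'
#' @param score numeric vector or `score_vector`.
#' @param cohort a `cohort_table`.
#' @return A `km_split`: per-group curves (`high`, `low`), `chisq`, `p`,
#'   `median_cut`, group sizes.
#' @export
km_median_split <- function(score, cohort) {
  al <- align_score_cohort(score, cohort)
  s <- as.numeric(al$score)
  co <- al$cohort
  med <- stats::median(s)
  high <- s >= med
  if (all(high) || !any(high))
    stop_prognode("degenerate_split", "median split leaves one group empty")
  if (sum(co$dmfs_event) == 0L)
    stop_prognode("undefined_statistic", "all observations censored; log-rank undefined")
  grp <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  sd_test <- survival::survdiff(
    survival::Surv(co$dmfs_time, co$dmfs_event) ~ grp)
  structure(list(
    high = km_curve(co$dmfs_time[high], co$dmfs_event[high]),
    low = km_curve(co$dmfs_time[!high], co$dmfs_event[!high]),
    chisq = unname(sd_test$chisq),
    p = stats::pchisq(sd_test$chisq, df = 1L, lower.tail = FALSE),
    median_cut = med,
    n = c(low = sum(!high), high = sum(high)),
    signature = attr(score, "signature") %||% "score"
  ), class = "km_split")
}

#' @export
print.km_split <- function(x, ...) {
  cat(sprintf("median-split KM (%s): cut=%.3f, n=%d/%d, log-rank chisq=%.3f, p=%.3g\n",
              x$signature, x$median_cut, x$n[["low"]], x$n[["high"]],
              x$chisq, x$p))
  invisible(x)
}

#' @export
plot.km_split <- function(x, main = NULL, ...) {
  xmax <- max(c(x$high$time, x$low$time, 1))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = "months", ylab = "DMFS probability",
                 main = main %||% sprintf("%s, median split", x$signature))
  for (g in c("low", "high")) {
    cv <- x[[g]]
    graphics::lines(stats::stepfun(cv$time, c(1, cv$surv)),
                    do.points = FALSE,
                    col = if (g == "high") "firebrick" else "navy")
  }
  graphics::legend("bottomleft", c("low score", "high score"),
                   col = c("navy", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
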