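# Independent oracles used across tests. These deliberately use plain loops
# and closed forms, never the package's own code paths.

# Harrell concordance by full pair enumeration.
concordance_brute <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Cox log partial likelihood for distinct event times (tie corrections moot).
cox_logpl <- function(beta, z, time, event) {
  s <- 0
  for (i in which(event == 1)) {
    at_risk <- time >= time[i]
    s <- s + beta * z[i] - log(sum(exp(beta * z[at_risk])))
  }
  s
}

cox_beta_grid <- function(z, time, event) {
  stats::optimize(function(b) cox_logpl(b, z, time, event),
                  interval = c(-20, 20), maximum = TRUE, tol = 1e-9)$maximum
}

# GSEA running sum, step by step.
es_step_by_step <- function(metric, hit, p = 1) {
  N <- length(metric)
  NH <- sum(hit)
  sumw <- sum(abs(metric[hit])^p)
  run <- 0
  runs <- numeric(N)
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) abs(metric[i])^p / sumw else -1 / (N - NH)
    runs[i] <- run
  }
  runs[which.max(abs(runs))]
}

# Tiny cohort constructor for survival tests.
toy_cohort <- function(time, event, ln = NULL, ids = NULL) {
  n <- length(time)
  ids <- ids %||% sprintf("T%03d", seq_len(n))
  prognode::cohort_table(data.frame(
    sample_id = ids, er_status = "positive", her2_status = "negative",
    ln_status = ln %||% rep("negative", n),
    dmfs_time = time, dmfs_event = event, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small Z-scaled expression matrix with given rownames.
toy_zmat <- function(values, genes, samples = NULL) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE)
  rownames(m) <- genes
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  prognode::expression_matrix(m, scale = "zscore")
}
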