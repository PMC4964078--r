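#' Default latent expression programs
#'
#' Four biological programs whose activities drive both expression and
#' hazard in the generator, named after the processes the node-stratified
#' biology revolves around. Member genes reuse real signature symbols
#' (proliferation genes shared with the recurrence-score and subtype
#' signatures; immune / epigenetic / EMT genes drawn from the directional
#' signature), so the bundled signatures can be scored on synthetic cohorts.
#'
#' @return named list of character vectors.
#' @export
default_programs <- function() {
  list(
    proliferation = c("MKI67", "CCNB1", "BIRC5", "MYBL2", "AURKA",
                      "UBE2C", "RRM2", "CDC20", "CENPF", "KIF2C"),
    immune = c("CXCL12", "JAK1", "HLA-DPA1", "FOS", "PCBP2",
               "EGR1", "JUN", "ZFP36", "DUSP1", "CIRBP"),
    epigenetic = c("NAT10", "H3F3A", "SFN", "KRT10", "S100P",
                   "ARF6", "CSTA", "FLOT1", "SQLE", "COX5B"),
    emt = c("MMP11", "SERPINB3", "MTDH", "JTB", "S100G",
            "ACTC1", "MB", "SPDEF", "TXN", "SNRPE")
  )
}

#' Default per-stratum hazard effects of the latent programs
#'
#' Per-SD log-hazard effects for each program, separately in the LN-negative
#' and LN-positive strata. The defaults plant the node-dependent biology the
#' generator is built to emulate: an immune program protective only in LN+
#' disease, and adverse epigenetic/proliferative programs weighted toward
#' LN- disease.
#'
#' @return named list of `c(ln_neg =, ln_pos =)` vectors.
#' @export
default_effects <- function() {
  list(
    proliferation = c(ln_neg = 0.8, ln_pos = 0.3),
    immune = c(ln_neg = 0.0, ln_pos = -0.8),
    epigenetic = c(ln_neg = 0.6, ln_pos = 0.1),
    emt = c(ln_neg = 0.1, ln_pos = 0.6)
  )
}

# Gene universe: every bundled signature gene plus numbered filler genes.
default_gene_universe <- function(n_genes) {
  sig_genes <- unique(c(
    load_builtin("oncotype")$genes$symbol,
    rownames(load_builtin("pam50")$centroids),
    load_builtin("ellen")$genes$symbol
  ))
  if (n_genes < length(sig_genes))
    stop_prognode("invalid_input",
                  sprintf("n_genes must be >= %d to host all signature genes",
                          length(sig_genes)))
  extra <- n_genes - length(sig_genes)
  c(sig_genes, if (extra > 0) sprintf("FILLER%04d", seq_len(extra)))
}

#' Configure a synthetic ER+/HER2- cohort
#'
#' Defines the study-like generating conditions: cohort size, LN+ fraction,
#' latent expression programs with per-stratum per-SD log-hazard effects, a
#' Weibull baseline over a 120-month (10-year DMFS) horizon with
#' administrative censoring at 120 months, and random dropout.
#'
#' @param n_samples cohort size (default 300).
#' @param n_genes number of genes (default 400; must cover the bundled
#'   signature genes, which are embedded in the universe).
#' @param ln_positive_fraction probability a sample is LN+ (default 0.4).
#' @param programs named list of member-gene vectors (default
#'   [default_programs()]).
#' @param effects named list (same names as `programs`) of per-SD log-hazard
#'   effects `c(ln_neg=, ln_pos=)`.
#' @param weibull_shape,weibull_scale baseline event-time distribution in
#'   months (defaults 1.2 and 220, giving roughly a third of samples a
#'   10-year event under the null).
#' @param admin_censor administrative censoring horizon in months (120).
#' @param dropout_rate exponential random-dropout rate per month (default
#'   0.001).
#' @param noise_sd per-gene Gaussian noise SD on the log2 scale (default 0.5).
#' @param seed integer seed.
#' @return A `sim_config`.
#' @export
simulation_config <- function(n_samples = 300, n_genes = 400,
                              ln_positive_fraction = 0.4,
                              programs = default_programs(),
                              effects = default_effects(),
                              weibull_shape = 1.2, weibull_scale = 220,
                              admin_censor = 120, dropout_rate = 0.001,
                              noise_sd = 0.5, seed = 1) {
  problems <- character(0)
  if (!is.numeric(n_samples) || n_samples < 2) problems <- c(problems, "n_samples")
  if (ln_positive_fraction < 0 || ln_positive_fraction > 1)
    problems <- c(problems, "ln_positive_fraction")
  if (!setequal(names(programs), names(effects)))
    problems <- c(problems, "programs/effects name mismatch")
  if (!all(vapply(effects, function(e)
    all(is.finite(e)) && all(c("ln_neg", "ln_pos") %in% names(e)), logical(1))))
    problems <- c(problems, "effects")
  if (weibull_shape <= 0 || weibull_scale <= 0)
    problems <- c(problems, "weibull parameters")
  if (admin_censor <= 0) problems <- c(problems, "admin_censor")
  if (dropout_rate < 0) problems <- c(problems, "dropout_rate")
  if (noise_sd < 0) problems <- c(problems, "noise_sd")
  if (length(problems))
    stop_prognode("invalid_input",
                  paste("invalid simulation config:", paste(problems, collapse = ", ")))
  all_members <- unlist(programs, use.names = FALSE)
  if (anyDuplicated(all_members))
    warning("program gene sets overlap; overlapping genes load on several programs")
  structure(list(
    n_samples = n_samples, n_genes = n_genes,
    ln_positive_fraction = ln_positive_fraction,
    programs = programs, effects = effects,
    weibull_shape = weibull_shape, weibull_scale = weibull_scale,
    admin_censor = admin_censor, dropout_rate = dropout_rate,
    noise_sd = noise_sd, seed = seed
  ), class = "sim_config")
}

#' Simulate an ER+/HER2- cohort with LN-dependent hazard effects
#'
#' Per sample: program activities are standard normal; expression =
#' per-gene baseline (uniform 6-10, log2-like) + loading x activity +
#' Gaussian noise; LN status is Bernoulli; the true linear predictor is
#' `eta = sum_p effect_p[stratum] * activity_p`; event times come from
#' inverting the Weibull baseline survival scaled by `exp(eta)`; observed
#' time is the minimum of event, dropout, and the 120-month horizon. The
#' full generating truth (activities, eta, uncensored event times, loadings,
#' informative genes with marginal directions) is recorded.
#'
#' @param config a [simulation_config()].
#' @return A `synthetic_cohort`: `expression` (log2 `expr_matrix`),
#'   `clinical` (`cohort_table`), `truth`, `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  if (!inherits(config, "sim_config"))
    stop_prognode("invalid_input", "config must be a sim_config")
  with_seed(config$seed, {
    n <- config$n_samples
    genes <- default_gene_universe(config$n_genes)
    samples <- sprintf("S%04d", seq_len(n))
    P <- length(config$programs)
    act <- matrix(stats::rnorm(n * P), n, P,
                  dimnames = list(samples, names(config$programs)))
    ln_pos <- stats::rbinom(n, 1L, config$ln_positive_fraction) == 1L

    # expression
    baseline <- stats::runif(length(genes), 6, 10)
    v <- matrix(stats::rnorm(length(genes) * n, 0, config$noise_sd),
                length(genes), n, dimnames = list(genes, samples))
    v <- v + baseline
    loadings <- list()
    for (p in names(config$programs)) {
      members <- intersect(config$programs[[p]], genes)
      lo <- stats::setNames(stats::runif(length(members), 0.7, 1.3), members)
      loadings[[p]] <- lo
      v[members, ] <- v[members, ] + outer(lo, act[, p])
    }

    # survival
    eff <- vapply(config$effects, function(e)
      ifelse(ln_pos, e[["ln_pos"]], e[["ln_neg"]]), numeric(n))
    eta <- rowSums(eff * act)
    u <- stats::runif(n)
    t_event <- config$weibull_scale *
      (-log(u) * exp(-eta))^(1 / config$weibull_shape)
    t_drop <- if (config$dropout_rate > 0)
      stats::rexp(n, config$dropout_rate) else rep(Inf, n)
    obs <- pmin(t_event, t_drop, config$admin_censor)
    event <- as.integer(t_event <= pmin(t_drop, config$admin_censor))

    clinical <- cohort_table(data.frame(
      sample_id = samples,
      er_status = "positive",
      her2_status = "negative",
      ln_status = ifelse(ln_pos, "positive", "negative"),
      dmfs_time = pmax(obs, 1e-3),
      dmfs_event = event,
      stringsAsFactors = FALSE
    ))

    # marginal direction of each informative gene: sign of its loading times
    # the LN-fraction-weighted average hazard effect of its program
    f <- config$ln_positive_fraction
    info <- do.call(rbind, lapply(names(config$programs), function(p) {
      w <- (1 - f) * config$effects[[p]][["ln_neg"]] +
        f * config$effects[[p]][["ln_pos"]]
      lo <- loadings[[p]]
      data.frame(gene = names(lo), program = p,
                 direction = ifelse(lo * w > 0, "poor",
                                    ifelse(lo * w < 0, "good", "none")),
                 stringsAsFactors = FALSE)
    }))

    structure(list(
      expression = expression_matrix(v, scale = "log2"),
      clinical = clinical,
      truth = list(activities = act, eta = eta, event_time_true = t_event,
                   loadings = loadings, informative = info,
                   ln_positive = ln_pos, seed = config$seed),
      config = config
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d samples (%d LN+), %d genes, %d events (seed %d)\n",
              nrow(x$clinical), sum(x$clinical$ln_status == "positive"),
              nrow(x$expression$values), sum(x$clinical$dmfs_event),
              x$config$seed))
  invisible(x)
}

#' Add a probe layer over a synthetic cohort
#'
#' Each gene emits 1 to `probes_per_gene` probes: gene value + per-probe
#' constant offset + per-entry noise. Optionally two designated HER2 probes
#' are appended, with a planted HER2-high subpopulation (bimodal
#' contaminant) for exercising the mixture-based HER2 call.
#'
#' @param cohort a `synthetic_cohort`.
#' @param probes_per_gene maximum probes per gene (>= 1).
#' @param seed integer seed.
#' @param probe_offset_sd SD of the per-probe constant offset (default 0.2).
#' @param probe_noise_sd SD of per-entry probe noise (default 0.1).
#' @param her2_probes append two designated HER2 probes (default TRUE).
#' @param her2_high_fraction fraction of samples in the planted HER2-high
#'   subpopulation (default 0).
#' @return list: `expression` (probe-keyed log2 `expr_matrix`), `probe_map`
#'   (data.frame `probe_id`, `gene`), `her2_probe_ids`,
#'   `her2_positive_truth` (sample ids), `seed`.
#' @export
make_probe_layer <- function(cohort, probes_per_gene = 2, seed = 1,
                             probe_offset_sd = 0.2, probe_noise_sd = 0.1,
                             her2_probes = TRUE, her2_high_fraction = 0) {
  if (probes_per_gene < 1)
    stop_prognode("invalid_input", "probes_per_gene must be >= 1")
  v <- cohort$expression$values
  with_seed(seed, {
    n_probes <- if (probes_per_gene == 1) rep(1L, nrow(v)) else
      sample.int(probes_per_gene, nrow(v), replace = TRUE)
    probe_gene <- rep(rownames(v), n_probes)
    probe_id <- paste0(probe_gene, "_at",
                       unlist(lapply(n_probes, seq_len), use.names = FALSE))
    m <- v[probe_gene, , drop = FALSE]
    m <- m + stats::rnorm(length(probe_id), 0, probe_offset_sd) +
      matrix(stats::rnorm(length(m), 0, probe_noise_sd), nrow(m), ncol(m))
    rownames(m) <- probe_id
    her2_ids <- character(0)
    her2_truth <- character(0)
    if (her2_probes) {
      her2_ids <- c("HER2_probe_1", "HER2_probe_2")
      base <- matrix(stats::rnorm(2L * ncol(v), 7, 0.5), 2L, ncol(v),
                     dimnames = list(her2_ids, colnames(v)))
      if (her2_high_fraction > 0) {
        n_high <- max(1L, round(her2_high_fraction * ncol(v)))
        high <- sample(colnames(v), n_high)
        base[, high] <- base[, high] + 5
        her2_truth <- high
      }
      m <- rbind(m, base)
    }
    list(expression = expression_matrix(m, scale = "log2"),
         probe_map = data.frame(probe_id = probe_id, gene = probe_gene,
                                stringsAsFactors = FALSE),
         her2_probe_ids = her2_ids,
         her2_positive_truth = her2_truth,
         seed = seed)
  })
}
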