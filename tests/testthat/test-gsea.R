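make_two_class <- function(n_genes = 50, n_per_class = 10, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * 2 * n_per_class), n_genes, 2 * n_per_class,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(2 * n_per_class))))
  labels <- factor(rep(c("event", "event_free"), each = n_per_class))
  list(m = m, labels = labels)
}

test_that("signal-to-noise ranking is floored, antisymmetric, deterministic", {
  d <- make_two_class(seed = 2)
  m <- d$m
  m["G001", ] <- 5                            # equal class means -> metric 0
  m["G002", d$labels == "event"] <- m["G002", d$labels == "event"] + 3  # planted
  r <- rank_by_signal_to_noise(m, d$labels)
  expect_identical(r$symbol[1], "G002")
  expect_equal(r$metric[r$symbol == "G001"], 0)

  # label swap negates every metric
  r2 <- rank_by_signal_to_noise(m, factor(d$labels,
                                          levels = rev(levels(d$labels))))
  expect_equal(setNames(r2$metric, r2$symbol)[r$symbol], -r$metric,
               ignore_attr = TRUE)

  # SD floor: a nearly constant gene cannot blow up the metric
  m["G003", ] <- c(rep(1, 10), rep(1.001, 10))
  r3 <- rank_by_signal_to_noise(m, d$labels)
  expect_lte(abs(r3$metric[r3$symbol == "G003"]),
             abs(1 - 1.001) / (0.2 + 0.2) + 1e-12)

  few <- m[, 1:5]
  expect_error(rank_by_signal_to_noise(few, d$labels[1:5]),
               class = "prognode_invalid_input")
})

test_that("a strongly shifted gene ranks first among 200", {
  set.seed(3)
  m <- matrix(rnorm(200 * 24), 200, 24,
              dimnames = list(sprintf("G%03d", 1:200), sprintf("s%02d", 1:24)))
  labels <- factor(rep(c("up", "down"), each = 12), levels = c("up", "down"))
  m["G117", labels == "up"] <- m["G117", labels == "up"] + 3
  r <- rank_by_signal_to_noise(m, labels)
  expect_identical(r$symbol[1], "G117")
})

test_that("enrichment score equals the step-by-step running sum", {
  ranked <- structure(
    data.frame(symbol = sprintf("G%02d", 1:10),
               metric = c(2.5, 1.8, 1.2, 0.7, 0.3, -0.2, -0.8, -1.1, -1.9, -2.6)),
    class = c("ranked_list", "data.frame"))
  set.seed(4)
  for (i in 1:10) {
    gs <- sample(ranked$symbol, 3)
    er <- enrichment_score(ranked, gs)
    expect_equal(er$es, es_step_by_step(ranked$metric, ranked$symbol %in% gs))
    expect_lt(abs(er$running_sum[10]), 1e-12)   # increments and decrements balance
    expect_lte(abs(er$es), 1)
    expect_equal(er$n_genes, 3)
  }

  # analytic limits: singleton sets at the extremes of the list
  expect_equal(enrichment_score(ranked, "G01")$es, 1)
  expect_equal(enrichment_score(ranked, "G10")$es, -1)

  expect_error(enrichment_score(ranked, c("NOPE1", "NOPE2")),
               class = "prognode_empty_overlap")
  expect_error(enrichment_score(ranked, ranked$symbol),
               class = "prognode_degenerate_set")
})

test_that("enrichment score agrees with an independent implementation", {
  d <- make_two_class(n_genes = 80, seed = 5)
  r <- rank_by_signal_to_noise(d$m, d$labels)
  set.seed(6)
  stats_vec <- setNames(r$metric, r$symbol)
  for (i in 1:5) {
    gs <- sample(r$symbol, 8)
    ours <- enrichment_score(r, gs)$es
    ref <- fgsea::calcGseaStat(stats_vec,
                               selectedStats = which(r$symbol %in% gs),
                               gseaParam = 1, scoreType = "std")
    expect_equal(ours, unname(ref), tolerance = 1e-10)
  }
})

test_that("with p = 0 the score depends on ranks only", {
  d <- make_two_class(n_genes = 60, seed = 7)
  r <- rank_by_signal_to_noise(d$m, d$labels)
  set.seed(8)
  gs <- sample(r$symbol, 6)
  es0 <- enrichment_score(r, gs, p = 0)$es
  r2 <- r
  r2$metric <- exp(r$metric)   # monotone transform, same order
  expect_equal(enrichment_score(r2, gs, p = 0)$es, es0)
  # with p = 1 the transform changes only the hit weights
  expect_false(isTRUE(all.equal(enrichment_score(r2, gs, p = 1)$es,
                                enrichment_score(r, gs, p = 1)$es)))
})

test_that("phenotype permutation recovers a planted module and is reproducible", {
  set.seed(9)
  n_genes <- 150; n <- 30
  m <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(sprintf("G%03d", 1:n_genes), sprintf("s%02d", 1:n)))
  labels <- factor(rep(c("event", "event_free"), each = n / 2))
  module <- sprintf("G%03d", 1:20)
  m[module, labels == "event"] <- m[module, labels == "event"] + 1.2
  sets <- c(list(PLANTED = module),
            setNames(lapply(1:30, function(i) sample(rownames(m), 15)),
                     paste0("DECOY", 1:30)))
  res <- gsea_permutation(m, labels, sets, n_perm = 100, seed = 10)
  expect_identical(res$name[which.max(abs(res$nes))], "PLANTED")
  expect_lte(res$p_value[res$name == "PLANTED"], 0.05)

  res2 <- gsea_permutation(m, labels, sets, n_perm = 100, seed = 10)
  expect_identical(res, res2)
  expect_error(gsea_permutation(m, labels, sets, n_perm = 5),
               class = "prognode_invalid_input")
})

test_that("stratified GSEA runs per LN stratum on outcome classes", {
  cfg <- simulation_config(n_samples = 120, n_genes = 150, seed = 12)
  co <- simulate_cohort(cfg)
  z <- z_standardize(co$expression)
  sets <- list(IMMUNE = default_programs()$immune,
               PROLIF = default_programs()$proliferation)
  res <- gsea_by_stratum(z, co$clinical, sets, n_perm = 25, seed = 3)
  expect_named(res, c("ln_neg", "ln_pos"))
  expect_equal(nrow(res$ln_neg), 2)
  expect_true(all(abs(res$ln_neg$es) <= 1, na.rm = TRUE))
})
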