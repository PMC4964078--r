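# 4-gene, 2-class, 6-sample toy with a from-scratch recomputation of the
# shrunken-centroid quantities.
nsc_toy <- function() {
  m <- matrix(c(5.0, 5.2, 4.8, 7.0, 7.3, 6.9,   # up in class B
                3.0, 3.1, 2.9, 3.0, 3.2, 2.8,   # flat
                9.0, 8.5, 9.2, 6.0, 6.2, 5.8,   # down in class B
                1.0, 1.4, 1.2, 1.1, 1.3, 1.2),  # flat
              nrow = 4, byrow = TRUE,
              dimnames = list(c("gUP", "gFLAT1", "gDOWN", "gFLAT2"),
                              paste0("s", 1:6)))
  labels <- factor(c("A", "A", "A", "B", "B", "B"))
  list(m = m, labels = labels)
}

nsc_toy_oracle <- function(m, labels, delta = 0) {
  n <- ncol(m); K <- 2
  xbar <- rowMeans(m)
  xa <- rowMeans(m[, labels == "A"]); xb <- rowMeans(m[, labels == "B"])
  s2 <- numeric(nrow(m))
  for (g in seq_len(nrow(m))) {
    s2[g] <- (sum((m[g, labels == "A"] - xa[g])^2) +
                sum((m[g, labels == "B"] - xb[g])^2)) / (n - K)
  }
  s <- sqrt(s2); s0 <- median(s)
  mk <- sqrt(1 / 3 - 1 / 6)
  dA <- (xa - xbar) / (mk * (s + s0))
  dB <- (xb - xbar) / (mk * (s + s0))
  soft <- function(d) sign(d) * pmax(abs(d) - delta, 0)
  list(d = cbind(A = dA, B = dB),
       d_shrunk = cbind(A = soft(dA), B = soft(dB)),
       shrunk_cen = cbind(A = xbar + mk * (s + s0) * soft(dA),
                          B = xbar + mk * (s + s0) * soft(dB)),
       s = s, s0 = s0)
}

test_that("shrunken-centroid training matches a from-scratch recomputation", {
  toy <- nsc_toy()
  for (delta in c(0, 0.5, 2)) {
    fit <- nsc_train(toy$m, toy$labels, delta = delta)
    orc <- nsc_toy_oracle(toy$m, toy$labels, delta = delta)
    expect_equal(unname(fit$d), unname(orc$d), tolerance = 1e-12)
    expect_equal(unname(fit$d_shrunk), unname(orc$d_shrunk), tolerance = 1e-12)
    expect_equal(unname(fit$shrunken_centroids), unname(orc$shrunk_cen),
                 tolerance = 1e-12)
    expect_equal(fit$s, setNames(orc$s, rownames(toy$m)), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("shrinkage limits behave analytically", {
  toy <- nsc_toy()
  fit0 <- nsc_train(toy$m, toy$labels, delta = 0)
  expect_equal(fit0$shrunken_centroids, fit0$class_centroids, tolerance = 1e-12)

  dmax <- max(abs(fit0$d))
  fit_inf <- nsc_train(toy$m, toy$labels, delta = dmax + 0.1)
  expect_length(fit_inf$surviving, 0)
  expect_equal(fit_inf$shrunken_centroids[, 1], fit_inf$overall_centroid)
  expect_equal(fit_inf$shrunken_centroids[, 2], fit_inf$overall_centroid)

  # with no surviving genes and unequal priors, every sample gets the majority class
  m <- toy$m[, c(1:3, 4:6, 4:6)]
  colnames(m) <- paste0("s", 1:9)
  lab <- factor(c("A", "A", "A", rep("B", 6)))
  f <- nsc_train(m, lab, delta = max(abs(nsc_train(m, lab, 0)$d)) + 1)
  pred <- nsc_predict(f, m)
  expect_true(all(pred$class == "B"))

  # number of surviving genes is non-increasing in delta
  ns <- vapply(seq(0, dmax, length.out = 12), function(d)
    length(nsc_train(toy$m, toy$labels, d)$surviving), integer(1))
  expect_true(all(diff(ns) <= 0))

  expect_error(nsc_train(toy$m, factor(rep("A", 6)), 0),
               class = "prognode_invalid_input")
})

test_that("prediction equals brute-force discriminant evaluation", {
  toy <- nsc_toy()
  fit <- nsc_train(toy$m, toy$labels, delta = 0.3)
  set.seed(14)
  x <- rnorm(4, 5, 3); names(x) <- rownames(toy$m)
  pred <- nsc_predict(fit, x)
  # brute force
  idx <- match(fit$surviving, fit$gene_ids)
  brute <- vapply(seq_along(fit$classes), function(j) {
    sum((x[fit$surviving] - fit$shrunken_centroids[idx, j])^2 /
          (fit$s[idx] + fit$s0)^2) - 2 * log(fit$priors[j])
  }, numeric(1))
  expect_equal(unname(pred$scores[1, ]), brute, tolerance = 1e-12)
  expect_identical(unname(pred$class), fit$classes[which.min(brute)])

  # a sample equal to a shrunken class centroid, equal priors, goes there
  cen <- fit$shrunken_centroids[, 2]
  names(cen) <- fit$gene_ids
  expect_identical(unname(nsc_predict(fit, cen)$class), "B")

  expect_error(nsc_predict(fit, x[-1]), class = "prognode_missing_feature")
})

test_that("delta = 0 reduces to a diagonal-covariance nearest-centroid rule", {
  set.seed(21)
  m <- matrix(rnorm(10 * 20), 10, 20,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  lab <- factor(rep(c("A", "B"), each = 10))
  m[1:3, lab == "B"] <- m[1:3, lab == "B"] + 2
  fit <- nsc_train(m, lab, delta = 0)
  set.seed(22)
  xs <- matrix(rnorm(10 * 7), 10, 7, dimnames = list(rownames(m), paste0("t", 1:7)))
  pred <- nsc_predict(fit, xs)$class
  # oracle: argmin_k sum (x - raw class centroid)^2 / (s + s0)^2 - 2 log pi
  ca <- rowMeans(m[, lab == "A"]); cb <- rowMeans(m[, lab == "B"])
  w <- (fit$s + fit$s0)^2
  oracle <- apply(xs, 2, function(x) {
    da <- sum((x - ca)^2 / w) - 2 * log(0.5)
    db <- sum((x - cb)^2 / w) - 2 * log(0.5)
    if (da <= db) "A" else "B"
  })
  expect_identical(unname(pred), unname(oracle))
})

test_that("cross-validation finds separable structure and is deterministic", {
  set.seed(31)
  n <- 40
  m <- matrix(rnorm(30 * n), 30, n,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:n)))
  lab <- factor(rep(c("A", "B"), each = n / 2))
  m[1:5, lab == "B"] <- m[1:5, lab == "B"] + 6   # clusters 6 SD apart
  cv1 <- nsc_cv(m, lab, k = 10, seed = 5)
  cv2 <- nsc_cv(m, lab, k = 10, seed = 5)
  expect_equal(min(cv1$errors), 0)
  expect_identical(cv1[c("delta_grid", "errors", "best_delta", "folds")],
                   cv2[c("delta_grid", "errors", "best_delta", "folds")])
  # ties broken toward the larger threshold
  expect_equal(cv1$best_delta, max(cv1$delta_grid[cv1$errors == min(cv1$errors)]))
  expect_error(nsc_cv(m, lab, delta_grid = numeric(0)),
               class = "prognode_invalid_input")
})

test_that("CV error under label noise stays near the majority-class rate", {
  n <- 60
  maj <- 36 / 60
  errs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    m <- matrix(rnorm(25 * n), 25, n,
                dimnames = list(paste0("g", 1:25), paste0("s", 1:n)))
    lab <- factor(sample(rep(c("A", "B"), c(36, 24))))
    cv <- nsc_cv(m, lab, delta_grid = seq(0, 3, length.out = 10), k = 5,
                 seed = s)
    min(cv$errors)
  }, numeric(1))
  expect_lt(abs(mean(errs) - (1 - maj)), 0.15)
})

test_that("derived signatures orient genes by their event-class centroid", {
  set.seed(41)
  n <- 30
  m <- matrix(rnorm(20 * n), 20, n,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:n)))
  lab <- factor(rep(c("event_free", "event"), each = n / 2),
                levels = c("event_free", "event"))
  m["g1", lab == "event"] <- m["g1", lab == "event"] + 3   # up in metastasis
  m["g2", lab == "event"] <- m["g2", lab == "event"] - 3   # up in remission
  fit <- nsc_train(m, lab, delta = 1)
  sig <- derive_signature(fit, "event")
  expect_identical(sig$genes$direction[sig$genes$symbol == "G1"], "poor")
  expect_identical(sig$genes$direction[sig$genes$symbol == "G2"], "good")

  starved <- nsc_train(m, lab, delta = max(abs(fit$d)) + 5)
  expect_error(derive_signature(starved, "event"),
               class = "prognode_empty_signature")
})
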