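# Build a Z-like matrix over all bundled signature genes with given values.
sig_gene_matrix <- function(n_samples = 3, fill = 0) {
  genes <- unique(c(load_builtin("oncotype")$genes$symbol,
                    rownames(load_builtin("pam50")$centroids),
                    load_builtin("ellen")$genes$symbol))
  m <- matrix(fill, length(genes), n_samples,
              dimnames = list(genes, sprintf("s%d", seq_len(n_samples))))
  m
}

test_that("weighted-group recurrence score is the fixture's linear form", {
  onc <- load_builtin("oncotype")
  m <- sig_gene_matrix(3)
  x <- expression_matrix(m, "zscore")
  expect_equal(unname(as.numeric(oncotype_rs(x, onc))), c(0, 0, 0))

  # proliferation genes at z=1 in sample 2 only: RS = prolif coefficient * 1
  prolif <- onc$genes$symbol[onc$genes$group == "proliferation"]
  m2 <- m; m2[prolif, 2] <- 1
  rs <- oncotype_rs(expression_matrix(m2, "zscore"), onc)
  expect_equal(unname(as.numeric(rs)),
               c(0, unname(onc$group_coefficients[["proliferation"]]), 0))

  # homogeneity: doubling every z doubles every RS
  set.seed(3)
  m3 <- sig_gene_matrix(4); m3[] <- rnorm(length(m3))
  rs1 <- as.numeric(oncotype_rs(expression_matrix(m3, "zscore"), onc))
  rs2 <- as.numeric(oncotype_rs(expression_matrix(2 * m3, "zscore"), onc))
  expect_equal(rs2, 2 * rs1)

  # full linear form, hand-evaluated
  groups <- split(seq_len(16), onc$genes$group)
  expected <- vapply(1:4, function(j) {
    sum(vapply(names(groups), function(g) {
      idx <- groups[[g]]
      onc$group_coefficients[[g]] *
        sum(onc$genes$weight[idx] * m3[onc$genes$symbol[idx], j])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(rs1, expected)

  m4 <- m3[setdiff(rownames(m3), "GRB7"), ]
  expect_error(oncotype_rs(expression_matrix(m4, "zscore"), onc),
               class = "prognode_missing_feature")
})

test_that("spearman correlation matches the rank formula and flags bad input", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, -x), -1)
  # untied case: 1 - 6*sum(d^2) / (n(n^2-1))
  a <- c(1, 2, 3, 4, 5); b <- c(2, 1, 4, 3, 5)
  d2 <- sum((rank(a) - rank(b))^2)
  expect_equal(spearman_rho(a, b), 1 - 6 * d2 / (5 * 24))
  expect_equal(spearman_rho(a, b), 0.8)
  expect_error(spearman_rho(a, rep(1, 5)), class = "prognode_undefined_correlation")
  expect_error(spearman_rho(a, b[1:4]), class = "prognode_invalid_input")
  expect_error(spearman_rho(a[1:2], b[1:2]), class = "prognode_invalid_input")
})

test_that("subtype-correlation ROR equals the hand-combined rho sum", {
  pam <- load_builtin("pam50")
  used <- setdiff(rownames(pam$centroids), pam$excluded_genes)
  m <- sig_gene_matrix(2)
  # sample 1 = LumA centroid over the used genes; sample 2 = noise
  m[used, 1] <- pam$centroids[used, "LumA"]
  set.seed(8)
  m[used, 2] <- rnorm(length(used))
  x <- expression_matrix(m, "zscore")
  ror <- prosigna_ror(x, pam)

  rho_oracle <- function(sample_vec, k)
    stats::cor(rank(sample_vec), rank(pam$centroids[used, k]))
  expected1 <- sum(vapply(names(pam$ror_coefficients), function(k)
    pam$ror_coefficients[[k]] * rho_oracle(m[used, 1], k), numeric(1)))
  expect_equal(unname(as.numeric(ror)[1]), expected1, tolerance = 1e-12)
  expect_equal(rho_oracle(m[used, 1], "LumA"), 1)

  # identical gene vectors give identical ROR
  m2 <- m; m2[, 2] <- m2[, 1]
  ror2 <- as.numeric(prosigna_ror(expression_matrix(m2, "zscore"), pam))
  expect_equal(ror2[1], ror2[2])

  # invariance under strictly increasing per-sample transforms
  m3 <- m; m3[used, ] <- exp(m3[used, ] / 2) + 3
  ror3 <- as.numeric(prosigna_ror(expression_matrix(m3, "zscore"), pam))
  expect_equal(ror3, unname(as.numeric(ror)), tolerance = 1e-12)

  # too few shared genes
  small <- expression_matrix(m[used[1:5], , drop = FALSE], "zscore")
  expect_error(prosigna_ror(small, pam), class = "prognode_missing_feature")
})

test_that("directional mean-Z index is the good-minus-poor average", {
  ell <- load_builtin("ellen")
  good <- ell$genes$symbol[ell$genes$direction == "good"]
  poor <- ell$genes$symbol[ell$genes$direction == "poor"]
  m <- sig_gene_matrix(3)
  expect_equal(unname(as.numeric(directional_mean_index(
    expression_matrix(m, "zscore"), ell))), c(0, 0, 0))

  m[good, 1] <- 1; m[poor, 1] <- -1
  sc <- directional_mean_index(expression_matrix(m, "zscore"), ell)
  expect_equal(unname(as.numeric(sc)[1]), 2)
  expect_identical(attr(sc, "orientation"), "higher_is_better")

  # small toy: 3 good, 2 poor genes, against independently computed means
  toy <- gene_signature("toy", data.frame(
    symbol = c("A", "B", "C", "D", "E"),
    direction = c("good", "good", "good", "poor", "poor")))
  z <- toy_zmat(c(0.5, -1,
                  1.0, 2,
                  -0.5, 0,
                  2.0, 1,
                  -2.0, -1), genes = c("A", "B", "C", "D", "E"))
  idx <- as.numeric(directional_mean_index(z, toy))
  expect_equal(idx, c(mean(c(0.5, 1, -0.5)) - mean(c(2, -2)),
                      mean(c(-1, 2, 0)) - mean(c(1, -1))))

  z2 <- toy_zmat(c(1, 1), genes = "A")
  expect_error(directional_mean_index(z2, toy), class = "prognode_missing_feature")
})

test_that("scores are permutation-equivariant over samples", {
  set.seed(10)
  m <- sig_gene_matrix(6); m[] <- rnorm(length(m))
  x <- expression_matrix(m, "zscore")
  perm <- sample(colnames(m))
  xp <- expression_matrix(m[, perm], "zscore")
  for (f in list(oncotype_rs, prosigna_ror, directional_mean_index)) {
    s <- f(x); sp <- f(xp)
    expect_equal(unclass(sp)[names(s)], unclass(s)[names(s)])
  }
})
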