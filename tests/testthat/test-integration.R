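# Definitional RV oracle: explicit trace formula with loops, independent
# of the crossprod shortcut in escoufier_rv().
rv_oracle <- function(A, B) {
  A <- scale(as.matrix(A), scale = FALSE)
  B <- scale(as.matrix(B), scale = FALSE)
  Sab <- t(A) %*% B
  Sba <- t(B) %*% A
  Saa <- t(A) %*% A
  Sbb <- t(B) %*% B
  tr <- function(M) sum(diag(M))
  tr(Sab %*% Sba) / sqrt(tr(Saa %*% Saa) * tr(Sbb %*% Sbb))
}

test_that("RV matches its trace definition, bounds and degenerate cases", {
  set.seed(21)
  A <- matrix(rnorm(40), 10, 4)
  B <- matrix(rnorm(30), 10, 3)
  expect_equal(escoufier_rv(A, B), rv_oracle(A, B), tolerance = 1e-12)
  expect_equal(escoufier_rv(A, A), 1, tolerance = 1e-12)
  # univariate blocks: RV = r^2
  x <- rnorm(12)
  y <- rnorm(12)
  expect_equal(escoufier_rv(cbind(x), cbind(y)), cor(x, y)^2, tolerance = 1e-12)
  # rotation within a block and global block rescaling leave RV unchanged
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  expect_equal(escoufier_rv(A %*% Q, B), escoufier_rv(A, B), tolerance = 1e-10)
  expect_equal(escoufier_rv(3.7 * A, 0.2 * B), escoufier_rv(A, B), tolerance = 1e-10)
  expect_error(escoufier_rv(matrix(1, 5, 2), B[1:5, ]), "zero-variance")
})

test_that("RV on the published population table reproduces the printed block statistics", {
  tab <- hynobius_populations()
  X <- tab[c("x1", "x2")]
  Y <- tab[c("y1", "y2", "y3")]
  expect_equal(escoufier_rv(X, Y), 0.4847, tolerance = 1e-4)
  expect_equal(escoufier_rv(tab["x1"], Y), 0.2481, tolerance = 1e-4)
  # the printed table's x2-block RV evaluates to 0.50646 (the published
  # rounding differs in the 4th decimal; see the methods vignette)
  expect_equal(escoufier_rv(tab["x2"], Y), 0.5064614, tolerance = 1e-6)
})

test_that("RV permutation test is seeded, add-one estimated, and detects dependence", {
  set.seed(22)
  A <- matrix(rnorm(60), 20, 3)
  B <- A + matrix(rnorm(60, sd = 1e-3), 20, 3)
  res <- rv_permutation_test(A, B, n_perm = 999, seed = 99)
  expect_equal(res$p_value, 1 / 1000) # no permutation beats the observed
  res2 <- rv_permutation_test(A, B, n_perm = 999, seed = 99)
  expect_identical(res$p_value, res2$p_value)
  expect_identical(res$perm_rv, res2$perm_rv)
  # permuted RVs hover near the null mean, far below the observed value
  expect_lt(mean(res$perm_rv), res$rv / 2)
  expect_error(rv_permutation_test(A, B, n_perm = 0), "at least 1")
})

test_that("two-block PLS satisfies the SVD contract", {
  set.seed(23)
  A <- matrix(rnorm(80), 16, 5)
  B <- matrix(rnorm(64), 16, 4)
  fit <- two_block_pls(A, B)
  expect_true(all(diff(fit$d) <= 1e-12))
  expect_equal(colSums(fit$loadings_a^2), rep(1, 4), tolerance = 1e-9)
  expect_equal(colSums(fit$loadings_b^2), rep(1, 4), tolerance = 1e-9)
  expect_equal(sum(fit$pct_sq_cov), 100, tolerance = 1e-6)
  # univariate blocks: PLS1 correlation is plain Pearson correlation
  x <- rnorm(15)
  y <- 0.5 * x + rnorm(15)
  uni <- two_block_pls(cbind(x), cbind(y))
  expect_equal(abs(uni$r_pls1), abs(cor(x, y)), tolerance = 1e-12)
  expect_equal(uni$pct_sq_cov, 100)
})

test_that("PLS on the published population table reproduces the printed axis correlations", {
  tab <- hynobius_populations()
  X <- tab[c("x1", "x2")]
  Y <- tab[c("y1", "y2", "y3")]
  expect_equal(two_block_pls(X, Y)$r_pls1, 0.7083, tolerance = 1e-4)
  expect_equal(two_block_pls(tab["x2"], Y)$r_pls1, 0.7213, tolerance = 1e-4)
  expect_equal(two_block_pls(tab["x1"], Y)$r_pls1, 0.5097, tolerance = 1e-4)
})

test_that("PLS permutation p is reproducible and small for dependent blocks", {
  set.seed(24)
  A <- matrix(rnorm(45), 15, 3)
  B <- A + matrix(rnorm(45, sd = 0.001), 15, 3)
  f1 <- two_block_pls(A, B, n_perm = 499, seed = 7)
  f2 <- two_block_pls(A, B, n_perm = 499, seed = 7)
  expect_identical(f1$p_value, f2$p_value)
  expect_equal(f1$p_value, 1 / 500)
})

test_that("PCA reproduces closed-form axes, conserves variance, reconstructs data", {
  # collinear data: one axis carries everything
  x <- 1:10
  col <- pca_scores(cbind(x, 2 * x + 3))
  expect_equal(col$pct_variance[1], 100, tolerance = 1e-9)
  expect_equal(col$values[2], 0, tolerance = 1e-9)
  # 2x2 closed-form eigenvector oracle for the major axis direction
  set.seed(25)
  X <- cbind(rnorm(30), rnorm(30, sd = 2))
  X[, 2] <- X[, 2] + 0.8 * X[, 1]
  S <- cov(X)
  lam <- (S[1, 1] + S[2, 2]) / 2 + sqrt(((S[1, 1] - S[2, 2]) / 2)^2 + S[1, 2]^2)
  slope_oracle <- (lam - S[1, 1]) / S[1, 2]
  p <- pca_scores(X)
  expect_equal(unname(p$loadings[2, 1] / p$loadings[1, 1]), slope_oracle, tolerance = 1e-9)
  # variance conservation and exact back-projection
  expect_equal(sum(p$values), sum(apply(X, 2, var)), tolerance = 1e-9)
  recon <- sweep(p$scores %*% t(p$loadings), 2, -p$center)
  expect_equal(unname(recon), unname(X), tolerance = 1e-9)
  # orientation convention: axis-1 sign follows the reference covariate
  up <- pca_scores(X, orient_by = X[, 2], orient_sign = 1)
  expect_gt(cor(up$scores[, 1], X[, 2]), 0)
  dn <- pca_scores(X, orient_by = X[, 2], orient_sign = -1)
  expect_lt(cor(dn$scores[, 1], X[, 2]), 0)
  expect_error(pca_scores(matrix(1, 4, 3)), "constant")
})
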