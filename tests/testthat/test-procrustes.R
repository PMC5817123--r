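test_that("centroid size matches its definition and scale covariance", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(sq), sqrt(2))
  set.seed(5)
  X <- random_config(20)
  expect_equal(centroid_size(2 * X), 2 * centroid_size(X))
  # direct formula oracle
  ctr <- colMeans(X)
  direct <- sqrt(sum((X[, 1] - ctr[1])^2 + (X[, 2] - ctr[2])^2))
  expect_equal(centroid_size(X), direct, tolerance = 1e-12)
  expect_error(centroid_size(rbind(c(1, 1), c(1, 1))), "coincide")
})

test_that("GPA removes similarity transforms and is order-invariant", {
  set.seed(7)
  base <- random_config(10)
  configs <- lapply(1:6, function(i) base + matrix(rnorm(20, sd = 0.05), 10, 2))
  aligned <- gpa(configs)
  expect_true(aligned$converged)
  # per-specimen coordinates centered, consensus unit size
  for (X in aligned$configs) expect_equal(colMeans(X), c(0, 0), tolerance = 1e-9)
  expect_equal(sum(aligned$consensus^2), 1, tolerance = 1e-9)
  # arbitrary per-specimen similarity transforms leave the solution
  # unchanged up to a global rotation
  set.seed(8)
  warped <- lapply(configs, function(X) {
    similarity_transform(X, runif(1, 0, 2 * pi), runif(1, 0.5, 3), rnorm(2, sd = 5))
  })
  aligned2 <- gpa(warped)
  expect_lt(procrustes_distance(aligned$consensus, aligned2$consensus), 1e-7)
  for (i in seq_along(configs)) {
    expect_lt(procrustes_distance(aligned$configs[[i]], aligned2$configs[[i]]), 1e-7)
  }
  # specimen order does not matter
  aligned3 <- gpa(configs[c(3, 1, 2, 6, 5, 4)])
  expect_lt(procrustes_distance(aligned$consensus, aligned3$consensus), 1e-9)
})

test_that("two similar configurations align to Procrustes distance zero", {
  set.seed(9)
  A <- random_config(12)
  B <- similarity_transform(A, 1.2, 2.5, c(3, -1))
  expect_lt(procrustes_distance(A, B), 1e-9)
  al <- gpa(list(A, B))
  expect_lt(al$rss, 1e-18)
})

test_that("2-configuration GPA agrees with the pairwise closed-form solution", {
  set.seed(10)
  A <- random_config(9)
  B <- random_config(9)
  al <- gpa(list(A, B))
  d_pair <- procrustes_distance(A, B)
  d_aligned <- sqrt(sum((al$configs[[1]] - al$configs[[2]])^2))
  expect_equal(d_aligned, d_pair, tolerance = 1e-8)
})

test_that("GPA attains a rotational minimum of the Procrustes sum of squares", {
  set.seed(12)
  configs <- lapply(1:5, function(i) random_config(8))
  al <- gpa(configs)
  rss_of <- function(configs, consensus) {
    sum(vapply(configs, function(X) sum((X - consensus)^2), 0))
  }
  for (angle in c(0.05, -0.1, 0.4)) {
    perturbed <- al$configs
    perturbed[[2]] <- similarity_transform(perturbed[[2]], angle)
    expect_gt(rss_of(perturbed, al$consensus), al$rss)
  }
})

test_that("GPA rejects mismatched landmark counts", {
  expect_error(gpa(list(random_config(5), random_config(6))), "landmark count")
})

test_that("Procrustes distance is symmetric, definite, and matches a grid search", {
  set.seed(13)
  A <- random_config(6)
  B <- random_config(6)
  C <- random_config(6)
  expect_equal(procrustes_distance(A, A), 0, tolerance = 1e-12)
  expect_equal(procrustes_distance(A, B), procrustes_distance(B, A), tolerance = 1e-12)
  expect_equal(procrustes_distance(A, B), grid_procrustes_distance(A, B), tolerance = 1e-5)
  # triangle inequality on random triples
  for (i in 1:20) {
    X <- random_config(6)
    Y <- random_config(6)
    Z <- random_config(6)
    expect_lte(
      procrustes_distance(X, Z),
      procrustes_distance(X, Y) + procrustes_distance(Y, Z) + 1e-12
    )
  }
  expect_error(procrustes_distance(random_config(5), random_config(6)), "counts differ")
})

test_that("bilateral symmetrization averages antimeres across the body axis", {
  # 2 midline points define the y axis; one asymmetric pair
  schema <- landmark_schema(
    rep("fixed", 4),
    pairs = rbind(c(3, 4)), midline = c(1L, 2L)
  )
  cfg <- rbind(c(0, 0), c(0, 2), c(1, 1), c(-1, 1.2))
  sym <- symmetrize_bilateral(cfg, schema)
  expect_equal(sym$full[3, ], c(1, 1.1), tolerance = 1e-12)
  expect_equal(sym$full[4, ], c(-1, 1.1), tolerance = 1e-12)
  expect_equal(sym$half_index, c(1L, 2L, 3L))
  # already symmetric configurations are fixed points
  sym2 <- symmetrize_bilateral(sym$full, schema)
  expect_equal(sym2$full, sym$full, tolerance = 1e-9)
  # idempotence in general
  set.seed(14)
  cfg3 <- cfg + matrix(rnorm(8, sd = 0.1), 4, 2)
  once <- symmetrize_bilateral(cfg3, schema)
  twice <- symmetrize_bilateral(once$full, schema)
  expect_equal(twice$full, once$full, tolerance = 1e-9)
  expect_error(
    symmetrize_bilateral(cfg, default_lateral_schema()),
    "pair map"
  )
})

test_that("principal-axis fallback picks the symmetry axis of wide configurations", {
  # wider than long: naive dominant axis would be transverse
  schema <- landmark_schema(
    rep("fixed", 5),
    pairs = rbind(c(2, 3), c(4, 5)), midline = 1L
  )
  cfg <- rbind(c(0, 1), c(-3, 0.5), c(3, 0.5), c(-2.8, -0.5), c(2.8, -0.5))
  sym <- symmetrize_bilateral(cfg, schema)
  expect_equal(sym$full, cfg, tolerance = 1e-9) # already symmetric, kept
})

test_that("mean shape is the renormalized coordinate-wise average", {
  set.seed(15)
  A <- random_config(7)
  pre <- function(X) {
    X <- sweep(X, 2, colMeans(X))
    X / sqrt(sum(X^2))
  }
  expect_equal(mean_shape(list(A)), pre(A), tolerance = 1e-12)
  B <- random_config(7)
  m <- (pre(A) + pre(B)) / 2
  expect_equal(mean_shape(list(pre(A), pre(B))), m / sqrt(sum(m^2)), tolerance = 1e-12)
  # GPA + mean of rotated copies of one shape recovers that shape
  copies <- lapply(seq(0.3, 1.8, length.out = 5), function(a) similarity_transform(A, a, 2))
  al <- gpa(copies)
  expect_lt(procrustes_distance(mean_shape(al), A), 1e-6)
  expect_error(mean_shape(list()), "empty group")
})
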