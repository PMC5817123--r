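test_that("skewness follows the population-moment definition", {
  expect_equal(skewness(c(-1, 0, 1)), 0)
  # direct evaluation: m3 = 2/27, m2 = 2/9
  expect_equal(skewness(c(0, 0, 1)), (2 / 27) / (2 / 9)^1.5, tolerance = 1e-12)
  expect_equal(skewness(c(0, 0, 1)), 0.70711, tolerance = 1e-5)
  set.seed(51)
  v <- rexp(40)
  expect_equal(skewness(-v), -skewness(v), tolerance = 1e-12)
  # bias-corrected variant scales by sqrt(n(n-1))/(n-2)
  n <- length(v)
  expect_equal(
    skewness(v, type = "sample"),
    skewness(v) * sqrt(n * (n - 1)) / (n - 2),
    tolerance = 1e-12
  )
  expect_error(skewness(rep(2, 5)), "zero variance")
  expect_error(skewness(c(1, 2)), "at least 3")
})

test_that("population statistics pool solitary specimens and join the census", {
  set.seed(52)
  scores <- dplyr::bind_rows(
    tibble::tibble(
      population = "g1", category = "NonCannibal",
      PC1_size = rnorm(10), PC1_shape = NA_real_
    ) |> dplyr::mutate(PC1_shape = -PC1_size), # exact negative correlation
    tibble::tibble(
      population = "g2", category = "NonCannibal",
      PC1_size = rnorm(8), PC1_shape = rnorm(8)
    ),
    tibble::tibble(
      population = c("t1", "t2", "t3"), category = "Solitary",
      PC1_size = rnorm(3), PC1_shape = rnorm(3)
    )
  )
  census <- tibble::tibble(
    tank_id = c("g1", "g2"), n_initial = 30,
    n_survivors = c(27, 24), n_cannibals = c(2, 3)
  )
  ps <- population_distribution_stats(scores, census)
  expect_equal(ps$population[1], "sol") # solitary pooled and listed first
  expect_equal(ps$x1[ps$population == "sol"], 0L)
  expect_equal(ps$y1[ps$population == "g1"], -1)
  expect_equal(ps$x1[ps$population == "g1"], 2L)
  expect_equal(ps$x2[ps$population == "g2"], 6L)
  # undersized populations are dropped with a warning
  scores$population[scores$population == "g2"][1:2] <- "tiny"
  expect_warning(
    ps2 <- population_distribution_stats(scores, census),
    "fewer than 3"
  )
  expect_false("tiny" %in% ps2$population)
})

test_that("solitary-style independent scores give near-zero joint correlation", {
  set.seed(53)
  y1s <- replicate(60, {
    cor(rnorm(30), rnorm(30))
  })
  expect_lt(median(abs(y1s)), 0.2)
  sc <- tibble::tibble(
    population = "sol", category = "Solitary",
    PC1_size = rnorm(200), PC1_shape = rnorm(200)
  )
  expect_lt(abs(population_distribution_stats(sc)$y1), 0.2)
})

test_that("census suite reproduces the published statistics and is seeded", {
  suite <- census_correlation_suite(hynobius_populations(), n_perm = 199, seed = 4)
  val <- function(s) suite$value[suite$statistic == s]
  expect_equal(val("RV(X,Y)"), 0.4847, tolerance = 1e-4)
  expect_equal(val("r_PLS1(X,Y)"), 0.7083, tolerance = 1e-4)
  expect_equal(val("RV(x1,Y)"), 0.2481, tolerance = 1e-4)
  expect_equal(val("r_PLS1(x1,Y)"), 0.5097, tolerance = 1e-4)
  expect_equal(val("r_PLS1(x2,Y)"), 0.7213, tolerance = 1e-4)
  expect_equal(val("r(x1,x2)"), 0.7652, tolerance = 1e-4)
  expect_equal(suite$t[suite$statistic == "r(x1,x2)"], 3.5657, tolerance = 1e-4)
  expect_equal(val("r(x2,y1)"), -0.6845, tolerance = 1e-4)
  expect_equal(val("r(x2,y3)"), -0.6035, tolerance = 1e-4)
  # these two evaluate differently from the published rounding when
  # recomputed from the printed columns (see the methods vignette)
  expect_equal(val("RV(x2,Y)"), 0.5064614, tolerance = 1e-6)
  expect_equal(val("r(x2,y2)"), 0.6603956, tolerance = 1e-6)
  suite2 <- census_correlation_suite(hynobius_populations(), n_perm = 199, seed = 4)
  expect_identical(suite$p_value, suite2$p_value)
})

test_that("planned-contrast ANOVA decomposes the among-group SS exactly", {
  set.seed(54)
  groups <- tibble::tibble(
    g = sprintf("p%d", 1:8),
    w = c(0, 1, 2, 3, 4, 5, 6, 7),
    mu = rnorm(8, sd = 2)
  )
  d <- tidyr::uncount(groups, 12) |>
    dplyr::mutate(v = mu + rnorm(dplyr::n()))
  av <- tidy(anova_planned_contrasts(d, v, g, w))
  ss <- function(t) av$ss[av$term == t]
  df <- function(t) av$df[av$term == t]
  expect_equal(ss("solitary_vs_rest") + ss("among_nonzero_victim"), ss("among_groups"),
    tolerance = 1e-9
  )
  expect_equal(ss("regression_slope") + ss("deviation_from_regression"), ss("among_groups"),
    tolerance = 1e-9
  )
  expect_equal(df("solitary_vs_rest") + df("among_nonzero_victim"), df("among_groups"))
  expect_equal(df("regression_slope") + df("deviation_from_regression"), df("among_groups"))
  # the regression row is tested against the deviation mean square
  expect_equal(av$df2[av$term == "regression_slope"], df("deviation_from_regression"))
  expect_equal(
    av$f[av$term == "regression_slope"],
    (ss("regression_slope") / 1) / (ss("deviation_from_regression") / df("deviation_from_regression")),
    tolerance = 1e-9
  )
})

test_that("group means exactly linear in victims leave no deviation SS", {
  set.seed(55)
  groups <- tibble::tibble(g = sprintf("p%d", 1:6), w = 0:5)
  d <- tidyr::uncount(groups, 10) |>
    dplyr::mutate(v = 2 + 0.7 * w) # constant within group, linear in victims
  d$v <- d$v + rep(rnorm(6, sd = 0), each = 10)
  av <- tidy(anova_planned_contrasts(d, v, g, w))
  expect_equal(av$ss[av$term == "deviation_from_regression"], 0, tolerance = 1e-9)
})

test_that("a shifted solitary mean is detected by the planned contrast", {
  set.seed(56)
  groups <- tibble::tibble(g = sprintf("p%d", 1:8), w = 0:7)
  d <- tidyr::uncount(groups, 15) |>
    dplyr::mutate(v = rnorm(dplyr::n()) + ifelse(w == 0, 2, 0))
  av <- tidy(anova_planned_contrasts(d, v, g, w))
  expect_lt(av$p_value[av$term == "solitary_vs_rest"], 0.01)
})

test_that("ANOVA input contracts are enforced", {
  d <- tibble::tibble(v = rnorm(12), g = rep(c("a", "b"), 6), w = rep(c(0, 1), 6))
  expect_error(anova_planned_contrasts(d, v, g, w), "at least 3 populations")
  d2 <- tibble::tibble(
    v = rnorm(12), g = rep(c("a", "b", "c"), each = 4),
    w = rep(c(0, 0, 1), each = 4)
  )
  expect_error(anova_planned_contrasts(d2, v, g, w), "exactly one zero-victim")
  d3 <- tibble::tibble(
    v = rnorm(12), g = rep(c("a", "b", "c"), each = 4),
    w = c(rep(0, 4), rep(1, 4), 1, 2, 2, 2) # mixed victims within group c
  )
  expect_error(anova_planned_contrasts(d3, v, g, w), "constant within")
})
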