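#' Moment coefficient of skewness
#'
#' `g1 = m3 / m2^(3/2)` with central moments using `1/n` denominators (the
#' population-moment form used for the per-tank size and shape skewness
#' statistics). The bias-corrected sample variant
#' `g1 * sqrt(n (n - 1)) / (n - 2)` is available via `type = "sample"`;
#' the raw specimen data behind published tables rarely state which form
#' was used, so both are provided.
#'
#' @param values Numeric vector, n >= 3, non-zero variance.
#' @param type `"moment"` (default) or `"sample"`.
#' @return A scalar; sign flips exactly when `values` is negated.
#' @export
#' @examples
#' skewness(c(-1, 0, 1)) # 0
#' skewness(c(0, 0, 1)) # 0.70711
skewness <- function(values, type = c("moment", "sample")) {
  type <- match.arg(type)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) abort("skewness needs at least 3 values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) abort("zero variance: skewness undefined")
  g1 <- mean((values - m)^3) / m2^1.5
  if (type == "sample") g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  g1
}

#' Per-population size/shape distribution statistics
#'
#' Summarises each tank population's joint size-shape score distribution by
#' the reaction-norm statistics vector `Y = (y1, y2, y3)`:
#' `y1 = r(PC1_size, PC1_shape)`, `y2 = sk(PC1_size)`,
#' `y3 = sk(PC1_shape)`. Solitary specimens are pooled into the single
#' hypothetical zero-victim population `"sol"` (they never interact, so
#' they stand in for a tank with no cannibals and no victims). Census
#' counts `x1` (cannibals) and `x2` (victims) are joined from `census`.
#'
#' @param scores Per-specimen tibble with columns `population`,
#'   `PC1_size`, `PC1_shape`, and optionally `category` (specimens whose
#'   category equals `solitary_label` are pooled as `"sol"`).
#' @param census Optional census tibble (`tank_id`, `n_cannibals`,
#'   `n_victims`) supplying `x1`, `x2` for the high-density tanks; `"sol"`
#'   always gets `x1 = x2 = 0`.
#' @param solitary_label Category label marking solitary specimens.
#' @param skew_type Passed to [skewness()].
#' @return A tibble with one row per population: `population`, `x1`, `x2`,
#'   `y1`, `y2`, `y3`, `n`. Populations with fewer than 3 specimens are
#'   dropped with a warning.
#' @export
population_distribution_stats <- function(scores, census = NULL,
                                          solitary_label = "Solitary",
                                          skew_type = "moment") {
  stopifnot(all(c("population", "PC1_size", "PC1_shape") %in% names(scores)))
  df <- tibble::as_tibble(scores)
  if ("category" %in% names(df)) {
    df$population <- ifelse(df$category == solitary_label, "sol", df$population)
  }
  small <- names(which(table(df$population) < 3))
  if (length(small)) {
    warn(sprintf(
      "dropping population(s) with fewer than 3 specimens: %s",
      paste(small, collapse = ", ")
    ))
    df <- df[!df$population %in% small, ]
  }
  if (nrow(df) == 0) abort("no populations with at least 3 specimens")
  out <- df |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      y1 = cor(.data$PC1_size, .data$PC1_shape),
      y2 = skewness(.data$PC1_size, type = skew_type),
      y3 = skewness(.data$PC1_shape, type = skew_type),
      n = dplyr::n(),
      .groups = "drop"
    )
  out$x1 <- 0L
  out$x2 <- 0L
  if (!is.null(census)) {
    census <- validate_census(census)
    idx <- match(out$population, census$tank_id)
    hit <- !is.na(idx)
    out$x1[hit] <- census$n_cannibals[idx[hit]]
    out$x2[hit] <- census$n_victims[idx[hit]]
  }
  # sol first, then tanks in census / alphabetical order
  out <- out[order(out$population != "sol", out$x2, out$population), ]
  out[c("population", "x1", "x2", "y1", "y2", "y3", "n")]
}

#' Census-versus-distribution correlation suite
#'
#' The full set of association statistics between the census block
#' `X = (x1, x2)` and the distribution-statistics block `Y = (y1, y2, y3)`
#' across populations: the block-level `RV` and first-axis PLS correlations
#' for `X` vs `Y` and for each census count separately, the Pearson
#' correlation between the two census counts (with its closed-form t-test),
#' and the separate correlations of the victim count with each element of
#' `Y`. All permutation p-values use `n_perm` row permutations of one
#' block and the add-one estimator.
#'
#' @param summaries A population summary tibble with columns `x1`, `x2`,
#'   `y1`, `y2`, `y3` (e.g. from [population_distribution_stats()] or
#'   [hynobius_populations()]); at least 4 rows.
#' @param n_perm Permutations per test (default 10000).
#' @param seed Optional integer seed; one stream drives the whole suite.
#' @return A tibble with columns `statistic`, `value`, `p_value`, and
#'   (for the census-count correlation) `t`, `df`.
#' @export
#' @examples
#' census_correlation_suite(hynobius_populations(), n_perm = 99, seed = 1)
census_correlation_suite <- function(summaries, n_perm = 10000, seed = NULL) {
  stopifnot(all(c("x1", "x2", "y1", "y2", "y3") %in% names(summaries)))
  if (nrow(summaries) < 4) abort("need at least 4 populations")
  X <- as.matrix(summaries[c("x1", "x2")])
  Y <- as.matrix(summaries[c("y1", "y2", "y3")])
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  perm_cor_p <- function(x, y) {
    obs <- cor(x, y)
    perm <- vapply(seq_len(n_perm), function(i) abs(cor(x, sample(y))), 0)
    (sum(perm >= abs(obs)) + 1) / (n_perm + 1)
  }
  row <- function(statistic, value, p_value, t = NA_real_, df = NA_real_) {
    tibble::tibble(statistic = statistic, value = value, p_value = p_value, t = t, df = df)
  }
  rv_xy <- rv_permutation_test(X, Y, n_perm)
  pls_xy <- two_block_pls(X, Y, n_perm)
  rv_x1 <- rv_permutation_test(X[, "x1", drop = FALSE], Y, n_perm)
  pls_x1 <- two_block_pls(X[, "x1", drop = FALSE], Y, n_perm)
  rv_x2 <- rv_permutation_test(X[, "x2", drop = FALSE], Y, n_perm)
  pls_x2 <- two_block_pls(X[, "x2", drop = FALSE], Y, n_perm)
  ct <- pearson_test(summaries$x1, summaries$x2)
  dplyr::bind_rows(
    row("RV(X,Y)", rv_xy$rv, rv_xy$p_value),
    row("r_PLS1(X,Y)", pls_xy$r_pls1, pls_xy$p_value),
    row("RV(x1,Y)", rv_x1$rv, rv_x1$p_value),
    row("r_PLS1(x1,Y)", pls_x1$r_pls1, pls_x1$p_value),
    row("RV(x2,Y)", rv_x2$rv, rv_x2$p_value),
    row("r_PLS1(x2,Y)", pls_x2$r_pls1, pls_x2$p_value),
    row("r(x1,x2)", ct$r, ct$p_value, t = ct$t, df = ct$df),
    row("r(x2,y1)", cor(summaries$x2, summaries$y1), perm_cor_p(summaries$x2, summaries$y1)),
    row("r(x2,y2)", cor(summaries$x2, summaries$y2), perm_cor_p(summaries$x2, summaries$y2)),
    row("r(x2,y3)", cor(summaries$x2, summaries$y3), perm_cor_p(summaries$x2, summaries$y3))
  )
}

#' Planned-contrast one-way ANOVA along the victim-count gradient
#'
#' One-way ANOVA of a per-specimen score across populations keyed by their
#' victim count, with the among-group sum of squares decomposed two ways:
#' (i) hierarchically into the 1-df contrast of the zero-victim (solitary)
#' population against the pooled remaining populations plus the remainder
#' among the nonzero-victim populations, and (ii) into a 1-df group-size-
#' weighted linear regression of the population means on victim count plus
#' the deviation from that regression. Both decompositions are exact
#' (component sums of squares add to the among-group sum of squares). The
#' regression-slope row is tested against the deviation mean square (its
#' natural error term for a trend-over-groups hypothesis); all other rows
#' are tested against the within-group mean square.
#'
#' @param data Per-specimen tibble.
#' @param value,population,victims Unquoted column names: the score, the
#'   population id, and the population's victim count (constant within a
#'   population; 0 identifies the solitary pseudo-population).
#' @return An object of class `"contrast_anova"`; `tidy()` gives rows
#'   (`among_groups`, `solitary_vs_rest`, `regression_slope`,
#'   `deviation_from_regression`, `among_nonzero_victim`, `within_groups`)
#'   with `ss`, `df`, `ms`, `f`, `df1`, `df2`, `p_value`.
#' @export
anova_planned_contrasts <- function(data, value, population, victims) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- as.character(rlang::eval_tidy(rlang::enquo(population), data))
  w <- rlang::eval_tidy(rlang::enquo(victims), data)
  keep <- is.finite(v)
  v <- v[keep]
  g <- g[keep]
  w <- w[keep]
  tab <- tibble::tibble(v = v, g = g, w = w) |>
    dplyr::group_by(.data$g) |>
    dplyr::summarise(
      n = dplyr::n(), mean = mean(.data$v), victims = .data$w[1],
      ss_within = sum((.data$v - mean(.data$v))^2), .groups = "drop"
    )
  if (any(tab$n < 2)) abort("each population needs at least 2 specimens")
  G <- nrow(tab)
  if (G < 3) abort("need at least 3 populations")
  per_group_w <- tapply(w, g, function(z) length(unique(z)))
  if (any(per_group_w != 1)) abort("victim count must be constant within a population")
  zero <- tab$victims == 0
  if (sum(zero) != 1) abort("exactly one zero-victim (solitary) population expected")
  if (sum(!zero) < 2) abort("need at least 2 nonzero-victim populations for the regression contrast")
  N <- sum(tab$n)
  grand <- sum(tab$n * tab$mean) / N
  ss_within <- sum(tab$ss_within)
  df_within <- N - G
  ss_among <- sum(tab$n * (tab$mean - grand)^2)
  # (i) hierarchical: solitary vs pooled rest, then among nonzero groups
  n0 <- tab$n[zero]
  m0 <- tab$mean[zero]
  n1 <- sum(tab$n[!zero])
  m1 <- sum(tab$n[!zero] * tab$mean[!zero]) / n1
  ss_sol <- n0 * (m0 - grand)^2 + n1 * (m1 - grand)^2
  ss_nonzero <- ss_among - ss_sol
  # (ii) weighted regression of group means on victim count
  fit <- lm(mean ~ victims, data = tab, weights = tab$n)
  ss_reg <- sum(tab$n * (fitted(fit) - grand)^2)
  ss_dev <- ss_among - ss_reg
  ms_within <- ss_within / df_within
  ms_dev <- ss_dev / (G - 2)
  mkrow <- function(term, ss, df, err_ms, err_df) {
    ms <- ss / df
    f <- ms / err_ms
    tibble::tibble(
      term = term, ss = ss, df = df, ms = ms, f = f,
      df1 = df, df2 = err_df, p_value = pf(f, df, err_df, lower.tail = FALSE)
    )
  }
  out <- dplyr::bind_rows(
    mkrow("among_groups", ss_among, G - 1, ms_within, df_within),
    mkrow("solitary_vs_rest", ss_sol, 1, ms_within, df_within),
    mkrow("regression_slope", ss_reg, 1, ms_dev, G - 2),
    mkrow("deviation_from_regression", ss_dev, G - 2, ms_within, df_within),
    mkrow("among_nonzero_victim", ss_nonzero, G - 2, ms_within, df_within),
    tibble::tibble(
      term = "within_groups", ss = ss_within, df = df_within,
      ms = ms_within, f = NA_real_, df1 = NA_real_, df2 = NA_real_,
      p_value = NA_real_
    )
  )
  structure(list(table = out, slope = coef(fit)[["victims"]]), class = "contrast_anova")
}

#' @export
print.contrast_anova <- function(x, ...) {
  cat("<contrast_anova>\n")
  print(x$table)
  invisible(x)
}

#' @export
tidy.contrast_anova <- function(x, ...) x$table
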