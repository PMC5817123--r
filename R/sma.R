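#' Standardized major axis (and major axis) line fits
#'
#' Symmetric line fitting for allometry-style relationships where neither
#' variable is an error-free predictor. The standardized major axis (SMA)
#' slope has the closed form `sign(cov(x, y)) * sd(y) / sd(x)` with
#' intercept `mean(y) - slope * mean(x)`; the major axis (MA) slope is the
#' direction of the first eigenvector of the 2 x 2 covariance matrix. SMA
#' is the default and the one used for the size-shape integration lines and
#' the census cannibal-victim trend line.
#'
#' @param data A data frame.
#' @param x,y Unquoted column names of the two variables.
#' @param group Optional unquoted grouping column; one line per group.
#' @param method `"sma"` (default) or `"ma"`.
#' @return An object of class `"sma_fit"`; `tidy()` returns one row per
#'   group with `slope`, `intercept`, `n`, `r`.
#' @export
#' @examples
#' sma_fit(hynobius_populations(), x1, x2)
sma_fit <- function(data, x, y, group = NULL, method = c("sma", "ma")) {
  method <- match.arg(method)
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  gq <- rlang::enquo(group)
  gv <- if (rlang::quo_is_null(gq)) {
    rep("all", length(xv))
  } else {
    as.character(rlang::eval_tidy(gq, data))
  }
  fits <- dplyr::bind_rows(lapply(split(seq_along(xv), gv), function(idx) {
    fit <- line_fit_core(xv[idx], yv[idx], method)
    tibble::tibble(
      group = gv[idx[1]], n = length(idx),
      slope = fit$slope, intercept = fit$intercept, r = fit$r
    )
  }))
  structure(
    list(fits = fits, method = method, data = tibble::tibble(x = xv, y = yv, group = gv)),
    class = "sma_fit"
  )
}

line_fit_core <- function(x, y, method) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) abort("line fit needs at least 3 points")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in x or y")
  r <- cor(x, y)
  slope <- if (method == "sma") {
    sg <- sign(cov(x, y))
    if (sg == 0) sg <- 1
    sg * sd(y) / sd(x)
  } else {
    S <- cov(cbind(x, y))
    v <- eigen(S, symmetric = TRUE)$vectors[, 1]
    v[2] / v[1]
  }
  list(slope = slope, intercept = mean(y) - slope * mean(x), r = r)
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf("<sma_fit: method %s>\n", toupper(x$method)))
  print(x$fits)
  invisible(x)
}

#' @export
tidy.sma_fit <- function(x, ...) x$fits

#' Pearson correlation test (closed form)
#'
#' Two-sided t-test of zero correlation with `t = r * sqrt(df) /
#' sqrt(1 - r^2)` and `df = n - 2`.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return A one-row tibble with `r`, `t`, `df`, `p_value`, `n`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) abort("correlation test needs at least 3 points")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in x or y")
  r <- cor(x, y)
  df <- n - 2
  t <- r * sqrt(df) / sqrt(1 - r^2)
  tibble::tibble(r = r, t = t, df = df, p_value = 2 * pt(-abs(t), df), n = n)
}

# Common-slope profile statistic: for a candidate common SMA slope b, the
# residual u = y - b x and axis score v = y + b x are uncorrelated within a
# group iff b is that group's SMA slope; the likelihood-ratio statistic
# aggregates -n_i * log(1 - r_uv_i^2) across groups.
sma_lr_stat <- function(b, stats) {
  sum(vapply(stats, function(s) {
    cuv <- s$syy - b^2 * s$sxx
    vu <- s$syy - 2 * b * s$sxy + b^2 * s$sxx
    vv <- s$syy + 2 * b * s$sxy + b^2 * s$sxx
    r2 <- cuv^2 / (vu * vv)
    r2 <- min(r2, 1 - 1e-15)
    -s$n * log(1 - r2)
  }, 0))
}

group_line_stats <- function(x, y, g) {
  lapply(split(seq_along(x), g), function(idx) {
    if (length(idx) < 3) abort("each group needs at least 3 points")
    if (sd(x[idx]) == 0 || sd(y[idx]) == 0) abort("a group has zero variance")
    list(
      n = length(idx),
      xbar = mean(x[idx]), ybar = mean(y[idx]),
      sxx = var(x[idx]), syy = var(y[idx]), sxy = cov(x[idx], y[idx])
    )
  })
}

#' Tests of common SMA slope and common elevation across groups
#'
#' `sma_common_slope_test()` estimates a single SMA slope shared by all
#' groups (by minimizing the profile likelihood-ratio statistic; the
#' residual and axis scores of each group are uncorrelated exactly at that
#' group's own slope) and tests slope homogeneity against a chi-square with
#' `groups - 1` degrees of freedom. `sma_elevation_test()` then tests, at
#' the common slope, whether the group elevations (intercepts) coincide,
#' using a Wald statistic with residual-variance-based standard errors that
#' account for the uncertainty of the common slope.
#'
#' @param data A data frame with at least 2 groups of n >= 3 points.
#' @param x,y,group Unquoted column names.
#' @param common_slope Optional slope at which to test elevations; by
#'   default the common-slope estimate.
#' @return An object of class `"sma_comparison"`: a one-row tibble-backed
#'   list with the statistic, `df`, `p_value`, and `common_slope`.
#' @export
sma_common_slope_test <- function(data, x, y, group) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  gv <- as.character(rlang::eval_tidy(rlang::enquo(group), data))
  stats <- group_line_stats(xv, yv, gv)
  if (length(stats) < 2) abort("need at least 2 groups")
  sgn <- sign(sum(vapply(stats, function(s) (s$n - 1) * s$sxy, 0)))
  if (sgn == 0) sgn <- 1
  # optimize over positive slopes of the dominant sign, on a log grid first
  lr_of <- function(logb) sma_lr_stat(sgn * exp(logb), stats)
  grid <- seq(log(1e-4), log(1e4), length.out = 61)
  best <- grid[which.min(vapply(grid, lr_of, 0))]
  opt <- optimize(lr_of, interval = c(best - 1, best + 1), tol = 1e-10)
  b_hat <- sgn * exp(opt$minimum)
  stat <- max(opt$objective, 0)
  df <- length(stats) - 1
  structure(
    list(
      test = "common_slope", statistic = stat, df = df,
      p_value = pchisq(stat, df, lower.tail = FALSE),
      common_slope = b_hat, groups = names(stats), stats = stats
    ),
    class = "sma_comparison"
  )
}

#' @rdname sma_common_slope_test
#' @export
sma_elevation_test <- function(data, x, y, group, common_slope = NULL) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  gv <- as.character(rlang::eval_tidy(rlang::enquo(group), data))
  stats <- group_line_stats(xv, yv, gv)
  if (length(stats) < 2) abort("need at least 2 groups")
  if (is.null(common_slope)) {
    cs <- sma_common_slope_test(data, {{ x }}, {{ y }}, {{ group }})
    common_slope <- cs$common_slope
  }
  b <- common_slope
  # slope variance from the curvature of the profile statistic at b
  h <- max(abs(b), 1) * 1e-4
  curv <- (sma_lr_stat(b + h, stats) - 2 * sma_lr_stat(b, stats) +
    sma_lr_stat(b - h, stats)) / h^2
  var_b <- if (is.finite(curv) && curv > 0) 2 / curv else Inf
  elev <- vapply(stats, function(s) s$ybar - b * s$xbar, 0)
  var_elev <- vapply(stats, function(s) {
    resvar <- s$syy - 2 * b * s$sxy + b^2 * s$sxx
    resvar / s$n + s$xbar^2 * var_b
  }, 0)
  w <- 1 / var_elev
  a_hat <- sum(w * elev) / sum(w)
  stat <- sum(w * (elev - a_hat)^2)
  df <- length(stats) - 1
  structure(
    list(
      test = "elevation", statistic = stat, df = df,
      p_value = pchisq(stat, df, lower.tail = FALSE),
      common_slope = b, elevations = elev, groups = names(stats)
    ),
    class = "sma_comparison"
  )
}

#' @export
print.sma_comparison <- function(x, ...) {
  cat(sprintf(
    "<sma_comparison: %s test, statistic = %.4f, df = %d, p = %.4g>\n",
    x$test, x$statistic, x$df, x$p_value
  ))
  invisible(x)
}

#' @export
glance.sma_comparison <- function(x, ...) {
  tibble::tibble(
    test = x$test, statistic = x$statistic, df = x$df,
    p_value = x$p_value, common_slope = x$common_slope
  )
}
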