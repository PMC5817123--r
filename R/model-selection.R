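#' Akaike weights
#'
#' Normalized model support weights `w_i = exp(-delta_i / 2) /
#' sum_j exp(-delta_j / 2)` with `delta_i = AIC_i - min(AIC)`. Weights sum
#' to one, are strictly decreasing in AIC, and are invariant to adding a
#' constant to all AIC values.
#'
#' @param aic Numeric vector of AIC values for the compared model set.
#' @return A tibble with columns `aic`, `delta_aic`, `w_aic`.
#' @export
#' @examples
#' akaike_weights(c(244.7364, 244.5961))
akaike_weights <- function(aic) {
  if (!is.numeric(aic) || length(aic) < 1 || any(!is.finite(aic))) {
    abort("aic must be a finite numeric vector")
  }
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  tibble::tibble(aic = aic, delta_aic = delta, w_aic = w / sum(w))
}

# Gaussian AIC with the full log-likelihood constant:
# AIC = n log(2 pi RSS / n) + n + 2 (k + 1), where k counts mean-structure
# coefficients and the +1 is the error variance. Matches stats::AIC on lm.
# RSS is floored at a scale-relative machine-precision level so that
# exactly interpolating nested models tie on fit and the 2k penalty breaks
# the tie, instead of meaningless log-of-rounding-error differences.
gaussian_aic <- function(rss, n, k, scale_ss = 1) {
  rss <- max(rss, scale_ss * 1e-20, 1e-300)
  n * log(2 * pi * rss / n) + n + 2 * (k + 1)
}

#' Covariate design for the exploitation / interference models
#'
#' The six competing descriptions of how the census counts shape the
#' largest cannibal's phenotype. Models 1-3 are exploitation models whose
#' single covariate estimates the number of victims consumed by the
#' largest cannibal: Model 1 (egalitarian) `X1 = x2 / x1`; Model 2
#' (semiexclusive, each other cannibal ate one victim) `X2 = x2 - x1`;
#' Model 3 (completely exclusive) `X3 = x2`. Models 4-6 are
#' interference(-exploitation) models built by stepwise addition:
#' `x1`; `x1 + x2`; `x1 + x2 + x1 * x2`.
#'
#' @param x1,x2 Census counts of cannibals and victims per population.
#' @param model_id Integer 1-6.
#' @return A tibble of covariate columns (no intercept column).
#' @export
build_exploitation_design <- function(x1, x2, model_id) {
  if (length(x1) != length(x2)) abort("x1 and x2 must have equal length")
  if (!model_id %in% 1:6) abort("model_id must be in 1..6")
  switch(model_id,
    {
      if (any(x1 == 0)) abort("Model 1 requires x1 > 0 for all populations")
      tibble::tibble(X1 = x2 / x1)
    },
    tibble::tibble(X2 = x2 - 1 * x1),
    tibble::tibble(X3 = x2 - 0 * x1),
    tibble::tibble(x1 = x1),
    tibble::tibble(x1 = x1, x2 = x2),
    tibble::tibble(x1 = x1, x2 = x2, x1_x2 = x1 * x2)
  )
}

#' Ordinary least squares fit with table-style AIC accounting
#'
#' Fits `response ~ 1 + design` by OLS and reports the Gaussian AIC with
#' `k` counting the mean-structure coefficients (intercept included), the
#' convention used in the model-comparison tables; the error variance is
#' the `+1` inside the AIC constant.
#'
#' @param design Data frame / matrix of covariates (no intercept column).
#' @param response Numeric response, one value per row of `design`.
#' @return A one-row tibble: `k`, `rss`, `aic`, plus a `coefficients`
#'   list-column.
#' @export
fit_linear_models <- function(design, response) {
  X <- as_block_matrix(design, "design")
  n <- length(response)
  if (nrow(X) != n) abort("design and response sizes differ")
  k <- ncol(X) + 1
  if (n <= k) abort("more parameters than observations")
  if (qr(cbind(1, X))$rank < k) abort("rank-deficient design")
  df <- data.frame(response = response, X)
  fit <- lm(response ~ ., data = df)
  rss <- sum(resid(fit)^2)
  tss <- sum((response - mean(response))^2)
  tibble::tibble(
    k = k, rss = rss, aic = gaussian_aic(rss, n, k, scale_ss = tss),
    coefficients = list(coef(fit))
  )
}

#' Nonlinear growth-form fit for scores versus victim count
#'
#' Least-squares fit of one of the two competing growth forms describing
#' how cannibal size/shape scores change with the victim count `x2`:
#' asymptotic `a + b (1 - exp(-c x2))` or nonasymptotic power
#' `a + b x2^c`. Estimation uses Levenberg-Marquardt least squares from a
#' grid of 25 starting values of the shape parameter `c` over
#' \[0.01, 5\] (with `b` started at the data trend), keeping the converged
#' fit with the lowest residual sum of squares.
#'
#' @param x2 Victim counts (>= 0).
#' @param response Score values, one per population.
#' @param form `"asymptotic"` or `"power"`.
#' @return A one-row tibble: `form`, `k`, `rss`, `aic`, and a
#'   `coefficients` list-column holding `a`, `b`, `c`.
#' @export
fit_nonlinear <- function(x2, response, form = c("asymptotic", "power")) {
  form <- match.arg(form)
  if (length(x2) != length(response)) abort("x2 and response sizes differ")
  if (any(x2 < 0)) abort("x2 must be non-negative")
  n <- length(x2)
  if (n < 4) abort("need at least 4 populations (more points than parameters)")
  fml <- if (form == "asymptotic") {
    response ~ a + b * (1 - exp(-c * x2))
  } else {
    response ~ a + b * ifelse(x2 > 0, x2^c, 0)
  }
  dat <- data.frame(x2 = x2, response = response)
  trend <- if (cov(x2, response) >= 0) 1 else -1
  b0 <- trend * max(sd(response), 1e-6)
  best <- NULL
  for (c0 in exp(seq(log(0.01), log(5), length.out = 25))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        fml,
        data = dat,
        start = list(a = mean(response), b = b0, c = c0),
        lower = c(a = -Inf, b = -Inf, c = 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14, ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(rss = rss, coef = coef(fit))
    }
  }
  if (is.null(best)) abort("nonlinear fit failed to converge from all starts")
  k <- 3
  tss <- sum((response - mean(response))^2)
  tibble::tibble(
    form = form, k = k, rss = best$rss,
    aic = gaussian_aic(best$rss, n, k, scale_ss = tss),
    coefficients = list(best$coef)
  )
}

#' Compare the asymptotic and power growth forms
#'
#' Fits both nonlinear forms of [fit_nonlinear()] to the same data and
#' ranks them by AIC with Akaike weights.
#'
#' @inheritParams fit_nonlinear
#' @return A `"model_comparison"` object (see
#'   [select_largest_cannibal_models()]).
#' @export
compare_growth_models <- function(x2, response) {
  fits <- dplyr::bind_rows(
    fit_nonlinear(x2, response, "asymptotic"),
    fit_nonlinear(x2, response, "power")
  )
  fits$model <- fits$form
  finish_comparison(fits[c("model", "k", "rss", "aic", "coefficients")])
}

finish_comparison <- function(fits) {
  w <- akaike_weights(fits$aic)
  fits$delta_aic <- w$delta_aic
  fits$w_aic <- w$w_aic
  # ties broken by lowest RSS then lowest k
  fits <- fits[order(fits$aic, fits$rss, fits$k), ]
  structure(list(table = fits), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(dplyr::select(x$table, -dplyr::any_of("coefficients")))
  invisible(x)
}

#' @export
tidy.model_comparison <- function(x, ...) x$table

#' @export
glance.model_comparison <- function(x, ...) {
  best <- x$table[which.min(x$table$aic), ]
  tibble::tibble(
    n_models = nrow(x$table), best_model = as.character(best$model),
    best_aic = best$aic, best_w_aic = best$w_aic
  )
}

#' Exploitation / interference model selection for the largest cannibals
#'
#' Fits the six competing exploitation and interference models (see
#' [build_exploitation_design()]) to a per-tank response — the size
#' (`PC1_size`) or shape (`PC1_shape`) score of the largest cannibal in
#' each tank — and compares them by AIC, delta AIC and Akaike weights.
#'
#' @param census Census tibble with columns `tank_id`, `n_cannibals`,
#'   `n_victims` (or `x1`/`x2`).
#' @param response Numeric response, one value per census row.
#' @param models Integer subset of 1:6 (default all six).
#' @return A `"model_comparison"` object; `tidy()` gives the table with
#'   `model`, `k`, `rss`, `aic`, `delta_aic`, `w_aic` and coefficient
#'   list-column.
#' @export
select_largest_cannibal_models <- function(census, response, models = 1:6) {
  if (all(c("tank_id", "n_initial", "n_survivors", "n_cannibals") %in% names(census))) {
    census <- validate_census(census)
  }
  x1 <- if ("n_cannibals" %in% names(census)) census$n_cannibals else census[["x1"]]
  x2 <- if ("n_victims" %in% names(census)) census$n_victims else census[["x2"]]
  if (is.null(x1) || is.null(x2)) {
    abort("census must provide n_cannibals/n_victims (or x1/x2) columns")
  }
  if (length(response) != length(x1)) abort("one response value per tank expected")
  if (length(x1) < 6) abort("need at least 6 tanks")
  fits <- dplyr::bind_rows(lapply(models, function(m) {
    design <- build_exploitation_design(x1, x2, m)
    out <- fit_linear_models(design, response)
    out$model <- m
    out
  }))
  finish_comparison(fits[c("model", "k", "rss", "aic", "coefficients")])
}

#' Largest cannibal per tank
#'
#' Identifies, within each tank, the cannibal specimen with the largest
#' size score (ties broken by head centroid size), and returns its size
#' and shape scores — the responses modelled by
#' [select_largest_cannibal_models()].
#'
#' @param scores Per-specimen tibble with columns `population` (tank),
#'   `category`, `PC1_size`, `PC1_shape`, and optionally `HeadCS`.
#' @param cannibal_label Category label identifying cannibals.
#' @return A tibble with one row per tank holding the largest cannibal's
#'   `specimen_id` (if present), `PC1_size` and `PC1_shape`.
#' @export
largest_cannibal_scores <- function(scores, cannibal_label = "Cannibal") {
  stopifnot(all(c("population", "category", "PC1_size", "PC1_shape") %in% names(scores)))
  df <- scores[scores$category == cannibal_label, ]
  if (nrow(df) == 0) abort("no cannibal specimens found")
  if (!"HeadCS" %in% names(df)) df$HeadCS <- 0
  df |>
    dplyr::group_by(.data$population) |>
    dplyr::arrange(dplyr::desc(.data$PC1_size), dplyr::desc(.data$HeadCS), .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}
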