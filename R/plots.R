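#' Plot aligned landmark configurations
#'
#' Scatter of all Procrustes-aligned specimens (grey) with the consensus
#' configuration overlaid.
#'
#' @param object An `"aligned_shapes"` object.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.aligned_shapes <- function(object, ...) {
  cons <- tibble::tibble(
    point = seq_len(nrow(object$consensus)),
    x = object$consensus[, 1], y = object$consensus[, 2]
  )
  ggplot2::ggplot(object$coords, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.8, colour = "grey40") +
    ggplot2::geom_point(data = cons, colour = "firebrick", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = "Procrustes-aligned configurations",
      subtitle = "red: consensus shape"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the PLS1 score plane
#'
#' Joint distribution of the first-axis scores of the two blocks, the
#' plane on which the single-dimension shape axis (its PC1) lives.
#'
#' @param object A `"pls_fit"`.
#' @param labels Optional point labels (e.g. morph category).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pls_fit <- function(object, labels = NULL, ...) {
  df <- tibble::tibble(
    pls1_a = object$scores_a[, 1], pls1_b = object$scores_b[, 1]
  )
  p <- if (is.null(labels)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$pls1_a, y = .data$pls1_b)) +
      ggplot2::geom_point(alpha = 0.7)
  } else {
    df$label <- labels
    ggplot2::ggplot(df, ggplot2::aes(
      x = .data$pls1_a, y = .data$pls1_b, colour = .data$label
    )) +
      ggplot2::geom_point(alpha = 0.7)
  }
  p +
    ggplot2::labs(
      x = "PLS1 (block A)", y = "PLS1 (block B)",
      title = sprintf(
        "PLS1 plane: %.1f%% of squared covariance, r = %.3f",
        object$pct_sq_cov[1], object$r_pls1
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a model comparison as Akaike weights
#'
#' @param object A `"model_comparison"`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.model_comparison <- function(object, ...) {
  df <- object$table
  df$model <- factor(df$model, levels = df$model[order(df$aic)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$w_aic)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "model", y = "Akaike weight", title = "Model support") +
    ggplot2::theme_minimal()
}

#' Plot canonical variate scores
#'
#' @param object A `"cva_fit"`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.cva_fit <- function(object, ...) {
  df <- object$scores
  if (!"CV2" %in% names(df)) df$CV2 <- 0
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$CV1, y = .data$CV2, colour = .data$group
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::stat_ellipse(level = 0.9, linewidth = 0.3) +
    ggplot2::labs(title = "Canonical variate scores") +
    ggplot2::theme_minimal()
}

#' Size-shape score plane by morph category
#'
#' The populational reaction-norm view: each specimen's `PC1_size` vs
#' `PC1_shape` score, coloured by category, with per-category SMA
#' integration lines.
#'
#' @param scores A score tibble from [integration_scores()] (columns
#'   `PC1_size`, `PC1_shape`, optionally `category`).
#' @param lines Draw per-category SMA lines (default TRUE when categories
#'   are present).
#' @return A ggplot.
#' @export
plot_size_shape <- function(scores, lines = "category" %in% names(scores)) {
  stopifnot(all(c("PC1_size", "PC1_shape") %in% names(scores)))
  has_cat <- "category" %in% names(scores)
  p <- if (has_cat) {
    ggplot2::ggplot(scores, ggplot2::aes(
      x = .data$PC1_size, y = .data$PC1_shape, colour = .data$category
    ))
  } else {
    ggplot2::ggplot(scores, ggplot2::aes(x = .data$PC1_size, y = .data$PC1_shape))
  }
  p <- p + ggplot2::geom_point(alpha = 0.7)
  if (lines && has_cat) {
    fits <- tidy(sma_fit(scores, PC1_size, PC1_shape, group = category))
    p <- p + ggplot2::geom_abline(
      data = fits,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept, colour = .data$group),
      linetype = 2
    )
  }
  p +
    ggplot2::labs(x = "PC1 size", y = "PC1 shape", title = "Size-shape integration") +
    ggplot2::theme_minimal()
}
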