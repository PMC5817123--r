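#' Escoufier's RV coefficient between two blocks of variables
#'
#' A multivariate generalization of the squared correlation measuring the
#' overall association between two blocks measured on the same specimens:
#' `RV = tr(Sxy Syx) / sqrt(tr(Sxx^2) tr(Syy^2))`, with `S` the centered,
#' unstandardized cross-product (covariance) matrices. RV lies in \[0, 1\],
#' equals `r^2` when both blocks are univariate, and is invariant to
#' rotations within a block and to rescaling a whole block.
#'
#' @param block_a,block_b Numeric matrices or data frames with equal row
#'   counts (rows = specimens). Each must contain at least one non-constant
#'   column.
#' @return The RV coefficient, a scalar in \[0, 1\].
#' @export
escoufier_rv <- function(block_a, block_b) {
  A <- as_block_matrix(block_a, "block_a")
  B <- as_block_matrix(block_b, "block_b")
  if (nrow(A) != nrow(B)) abort("blocks must have equal row counts")
  if (nrow(A) < 3) abort("RV needs at least 3 rows")
  A <- scale(A, scale = FALSE)
  B <- scale(B, scale = FALSE)
  if (sum(A^2) == 0) abort("zero-variance block: block_a is constant")
  if (sum(B^2) == 0) abort("zero-variance block: block_b is constant")
  Sab <- crossprod(A, B)
  Saa <- crossprod(A)
  Sbb <- crossprod(B)
  num <- sum(Sab^2) # = tr(Sab %*% t(Sab))
  num / sqrt(sum(Saa^2) * sum(Sbb^2))
}

#' Permutation test of RV = 0
#'
#' Breaks the row correspondence between the two blocks by permuting the
#' rows of one block and recomputing RV. The p-value uses the add-one
#' estimator `(b + 1) / (n + 1)` (never exactly zero), where `b` counts
#' permuted RV values at least as large as the observed one.
#'
#' @inheritParams escoufier_rv
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed making the test reproducible.
#' @return An object of class `"rv_test"` with fields `rv`, `p_value`,
#'   `n_perm`, and the permutation null values `perm_rv`.
#' @export
rv_permutation_test <- function(block_a, block_b, n_perm = 10000, seed = NULL) {
  if (n_perm < 1) abort("n_perm must be at least 1")
  observed <- escoufier_rv(block_a, block_b)
  A <- as_block_matrix(block_a)
  B <- as_block_matrix(block_b)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  n <- nrow(A)
  perm <- vapply(seq_len(n_perm), function(i) {
    escoufier_rv(A, B[sample.int(n), , drop = FALSE])
  }, 0)
  structure(
    list(
      rv = observed,
      p_value = (sum(perm >= observed) + 1) / (n_perm + 1),
      n_perm = n_perm,
      perm_rv = perm
    ),
    class = "rv_test"
  )
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.rv_test <- function(x, ...) {
  cat(sprintf(
    "<rv_test: RV = %.4f, p = %.4g (%d permutations)>\n",
    x$rv, x$p_value, x$n_perm
  ))
  invisible(x)
}

#' @export
glance.rv_test <- function(x, ...) {
  tibble::tibble(rv = x$rv, p_value = x$p_value, n_perm = x$n_perm)
}

#' Two-block partial least squares
#'
#' Singular value decomposition of the between-block covariance matrix.
#' Each singular vector pair defines a PLS axis; scores are the projections
#' of the centered blocks on their unit-norm loading vectors. The first
#' axis maximizes covariance between the blocks; `pct_sq_cov[1]` is the
#' percent of total squared covariance it captures, and `r_pls1` the
#' Pearson correlation of the paired first-axis scores. An optional
#' permutation test (permuting rows of one block) assesses `r_pls1`.
#'
#' @inheritParams rv_permutation_test
#' @param n_perm Number of permutations for the `r_pls1` test; 0 skips it.
#' @return An object of class `"pls_fit"` with fields `d` (singular
#'   values), `loadings_a`, `loadings_b` (unit-norm columns), `scores_a`,
#'   `scores_b`, `pct_sq_cov`, `r_pls1`, `p_value`, `n_perm`.
#' @export
two_block_pls <- function(block_a, block_b, n_perm = 0, seed = NULL) {
  A <- as_block_matrix(block_a, "block_a")
  B <- as_block_matrix(block_b, "block_b")
  if (nrow(A) != nrow(B)) abort("blocks must have equal row counts")
  if (nrow(A) < 3) abort("PLS needs at least 3 rows")
  fit <- pls_core(A, B)
  p_value <- NA_real_
  perm_r <- NULL
  if (n_perm > 0) {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit(restore_seed(old), add = TRUE)
      set.seed(seed)
    }
    n <- nrow(A)
    perm_r <- vapply(seq_len(n_perm), function(i) {
      abs(pls_core(A, B[sample.int(n), , drop = FALSE])$r_pls1)
    }, 0)
    p_value <- (sum(perm_r >= abs(fit$r_pls1)) + 1) / (n_perm + 1)
  }
  structure(
    c(fit, list(p_value = p_value, n_perm = n_perm, perm_r = perm_r)),
    class = "pls_fit"
  )
}

pls_core <- function(A, B) {
  Ac <- scale(A, scale = FALSE)
  Bc <- scale(B, scale = FALSE)
  if (sum(Ac^2) == 0 || sum(Bc^2) == 0) abort("zero-variance block")
  S <- crossprod(Ac, Bc) / (nrow(Ac) - 1)
  sv <- svd(S)
  scores_a <- Ac %*% sv$u
  scores_b <- Bc %*% sv$v
  d <- sv$d
  list(
    d = d,
    loadings_a = sv$u,
    loadings_b = sv$v,
    scores_a = scores_a,
    scores_b = scores_b,
    pct_sq_cov = 100 * d^2 / sum(d^2),
    r_pls1 = cor(scores_a[, 1], scores_b[, 1])
  )
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf(
    "<pls_fit: %d axes, PLS1 %.2f%% of squared covariance, r_PLS1 = %.4f>\n",
    length(x$d), x$pct_sq_cov[1], x$r_pls1
  ))
  invisible(x)
}

#' @export
tidy.pls_fit <- function(x, ...) {
  tibble::tibble(
    axis = seq_along(x$d),
    singular_value = x$d,
    pct_sq_cov = x$pct_sq_cov
  )
}

#' @export
glance.pls_fit <- function(x, ...) {
  tibble::tibble(
    r_pls1 = x$r_pls1, pct_sq_cov_1 = x$pct_sq_cov[1],
    p_value = x$p_value, n_perm = x$n_perm
  )
}

#' Principal component axes and scores
#'
#' Eigendecomposition of the covariance matrix of the centered columns.
#' Used both for the score-plane "major axis regression lines" (the PC1 of
#' a two-column score plane, e.g. the PLS1 plane giving `PC1_shape` and the
#' SVL-HeadCS plane giving `PC1_size`) and for dimension reduction before
#' canonical variate analysis. Covariance (not correlation) matrices are
#' used throughout, as is standard for shape data.
#'
#' Axis signs from an eigendecomposition are arbitrary; `orient_by` fixes
#' them by a reference covariate: each axis is flipped, if needed, so that
#' its scores correlate with the reference in the direction given by
#' `orient_sign` (axis 1 only). The pipeline orients `PC1_size` to increase
#' with centroid size and `PC1_shape` so cannibals score low.
#'
#' @param x Numeric matrix or data frame (>= 2 rows and columns).
#' @param orient_by Optional numeric reference covariate (length = rows).
#' @param orient_sign `+1` or `-1`: desired sign of `cor(PC1, orient_by)`.
#' @return An object of class `"pca_axes"` with `values` (eigenvalues,
#'   non-increasing), `loadings`, `scores`, `pct_variance`, `center`.
#' @export
pca_scores <- function(x, orient_by = NULL, orient_sign = 1) {
  X <- as_block_matrix(x, "x")
  if (nrow(X) < 2 || ncol(X) < 2) abort("PCA needs at least 2 rows and 2 columns")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (sum(Xc^2) == 0) abort("constant matrix: PCA undefined")
  S <- crossprod(Xc) / (nrow(Xc) - 1)
  eg <- eigen(S, symmetric = TRUE)
  values <- pmax(eg$values, 0)
  loadings <- eg$vectors
  scores <- Xc %*% loadings
  if (!is.null(orient_by)) {
    r1 <- suppressWarnings(cor(scores[, 1], orient_by))
    if (is.finite(r1) && sign(r1) != sign(orient_sign)) {
      loadings[, 1] <- -loadings[, 1]
      scores[, 1] <- -scores[, 1]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  rownames(loadings) <- colnames(X)
  structure(
    list(
      values = values,
      loadings = loadings,
      scores = scores,
      pct_variance = 100 * values / sum(values),
      center = ctr
    ),
    class = "pca_axes"
  )
}

#' @export
print.pca_axes <- function(x, ...) {
  cat(sprintf(
    "<pca_axes: %d axes, PC1 %.1f%% of variance>\n",
    length(x$values), x$pct_variance[1]
  ))
  invisible(x)
}

#' @export
tidy.pca_axes <- function(x, ...) {
  tibble::tibble(
    axis = seq_along(x$values),
    eigenvalue = x$values,
    pct_variance = x$pct_variance
  )
}
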