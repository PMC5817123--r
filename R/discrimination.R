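#' Permutation test of the Procrustes distance between two group mean shapes
#'
#' The observed statistic is the Procrustes distance between the two group
#' mean shapes (computed from already-aligned coordinates). The null
#' distribution is built by shuffling the group labels of the pooled
#' specimens and recomputing the between-mean distance; the p-value uses
#' the add-one estimator `(b + 1) / (n + 1)`.
#'
#' @param aligned An `"aligned_shapes"` object from [gpa()].
#' @param labels Group label per specimen, in the order of
#'   `aligned$configs` (or a named vector keyed by specimen id).
#' @param group_a,group_b The two labels to compare.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Optional integer seed.
#' @return A one-row tibble: `group_a`, `group_b`, `distance`, `p_value`,
#'   `n_perm`, `n_a`, `n_b`.
#' @export
procrustes_distance_permutation_test <- function(aligned, labels, group_a, group_b,
                                                 n_perm = 10000, seed = NULL) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  if (n_perm < 1) abort("n_perm must be at least 1")
  labels <- align_labels(aligned, labels)
  sel <- labels %in% c(group_a, group_b)
  if (sum(labels == group_a) < 1 || sum(labels == group_b) < 1) {
    abort("both groups must be present in labels")
  }
  configs <- aligned$configs[sel]
  lab <- labels[sel]
  dist_for <- function(lab) {
    ma <- mean_shape(configs[lab == group_a])
    mb <- mean_shape(configs[lab == group_b])
    procrustes_distance(ma, mb)
  }
  observed <- dist_for(lab)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  perm <- vapply(seq_len(n_perm), function(i) dist_for(sample(lab)), 0)
  tibble::tibble(
    group_a = group_a, group_b = group_b,
    distance = observed,
    p_value = (sum(perm >= observed) + 1) / (n_perm + 1),
    n_perm = n_perm,
    n_a = sum(lab == group_a), n_b = sum(lab == group_b)
  )
}

align_labels <- function(aligned, labels) {
  ids <- names(aligned$configs)
  if (!is.null(names(labels))) {
    missing <- setdiff(ids, names(labels))
    if (length(missing)) abort("labels missing for some specimens")
    labels <- labels[ids]
  }
  if (length(labels) != length(ids)) {
    abort("labels must match the number of aligned specimens")
  }
  as.character(labels)
}

#' All pairwise mean-shape comparisons
#'
#' Runs [procrustes_distance_permutation_test()] for every pair of group
#' labels, producing the distance/p-value matrix layout used to compare the
#' cannibal, noncannibal and solitary morph mean shapes.
#'
#' @inheritParams procrustes_distance_permutation_test
#' @return A tibble with one row per unordered label pair.
#' @export
group_distance_table <- function(aligned, labels, n_perm = 10000, seed = NULL) {
  labels <- align_labels(aligned, labels)
  groups <- unique(labels)
  if (length(groups) < 2) abort("need at least 2 groups")
  pairs <- utils::combn(groups, 2)
  dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(k) {
    procrustes_distance_permutation_test(
      aligned, labels, pairs[1, k], pairs[2, k],
      n_perm = n_perm,
      seed = if (is.null(seed)) NULL else seed + k
    )
  }))
}

#' Canonical variate analysis of aligned shapes
#'
#' Ordination maximizing between-group relative to pooled within-group
#' variation. Because Procrustes coordinates usually outnumber specimens,
#' the data are first reduced to a PCA subspace (by default the axes
#' covering 95% of variance, capped at `n - g - 1`), then the generalized
#' eigenproblem of the between-group vs pooled within-group covariance is
#' solved in whitened form, so canonical scores have identity pooled
#' within-group covariance. At most `g - 1` canonical axes are returned.
#'
#' @param x An `"aligned_shapes"` object or a numeric specimen-by-variable
#'   matrix.
#' @param labels Group label per specimen (each group >= 2 specimens).
#' @param n_pca_retain Number of PCA axes retained before the CVA; must be
#'   below `n - g`.
#' @return An object of class `"cva_fit"` with `eigenvalues`, `scores`
#'   (tibble with labels), `group_means` (canonical space), `loadings`
#'   (original variable space), `n_pca_retain`.
#' @export
cva <- function(x, labels, n_pca_retain = NULL) {
  if (inherits(x, "aligned_shapes")) {
    labels <- align_labels(x, labels)
    wide <- aligned_coord_matrix(x)
    ids <- wide$specimen_id
    X <- as.matrix(wide[, -1])
  } else {
    X <- as_block_matrix(x, "x")
    ids <- rownames(X) %||% sprintf("specimen_%d", seq_len(nrow(X)))
    labels <- as.character(labels)
  }
  n <- nrow(X)
  g <- length(unique(labels))
  if (g < 2) abort("need at least 2 groups")
  if (any(table(labels) < 2)) abort("each group needs at least 2 specimens")
  # PCA reduction
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc)
  pct <- cumsum(sv$d^2) / sum(sv$d^2)
  cap <- n - g - 1
  if (cap < 1) abort("too few specimens for CVA")
  if (is.null(n_pca_retain)) {
    n_pca_retain <- min(which(pct >= 0.95), cap)
  }
  if (n_pca_retain >= n - g) {
    abort("n_pca_retain must be smaller than n - g; choose a smaller value")
  }
  P <- sv$v[, seq_len(n_pca_retain), drop = FALSE]
  Z <- Xc %*% P
  # pooled within-group and between-group covariance
  W <- matrix(0, n_pca_retain, n_pca_retain)
  B <- matrix(0, n_pca_retain, n_pca_retain)
  grand <- colMeans(Z)
  for (lev in unique(labels)) {
    zi <- Z[labels == lev, , drop = FALSE]
    mi <- colMeans(zi)
    W <- W + crossprod(sweep(zi, 2, mi))
    B <- B + nrow(zi) * tcrossprod(mi - grand)
  }
  W <- W / (n - g)
  B <- B / (g - 1)
  ew <- eigen(W, symmetric = TRUE)
  if (min(ew$values) < max(ew$values) * 1e-10) {
    abort("within-group covariance is singular after reduction; use a smaller n_pca_retain")
  }
  Wmhalf <- ew$vectors %*% diag(1 / sqrt(ew$values), n_pca_retain) %*% t(ew$vectors)
  M <- Wmhalf %*% B %*% Wmhalf
  em <- eigen(M, symmetric = TRUE)
  n_axes <- min(g - 1, n_pca_retain)
  A <- Wmhalf %*% em$vectors[, seq_len(n_axes), drop = FALSE]
  scores <- Z %*% A
  colnames(scores) <- paste0("CV", seq_len(n_axes))
  sums <- rowsum(scores, labels)
  means <- sums / as.vector(table(labels)[rownames(sums)])
  structure(
    list(
      eigenvalues = pmax(em$values[seq_len(n_axes)], 0),
      scores = dplyr::bind_cols(
        tibble::tibble(specimen_id = ids, group = labels),
        tibble::as_tibble(scores)
      ),
      group_means = means,
      loadings = P %*% A,
      n_pca_retain = n_pca_retain
    ),
    class = "cva_fit"
  )
}

#' @export
print.cva_fit <- function(x, ...) {
  cat(sprintf(
    "<cva_fit: %d canonical axes (PCA subspace dim %d), eigenvalues %s>\n",
    length(x$eigenvalues), x$n_pca_retain,
    paste(signif(x$eigenvalues, 4), collapse = ", ")
  ))
  invisible(x)
}

#' @export
tidy.cva_fit <- function(x, ...) x$scores
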