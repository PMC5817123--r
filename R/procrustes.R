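#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances from each landmark (and
#' semilandmark) to the configuration centroid. Centroid size is the size
#' variable of geometric morphometrics: it is covariant with similarity
#' scale, `centroid_size(c * X) = c * centroid_size(X)`.
#'
#' @param config Landmark coordinates: a p x 2 matrix or a data frame with
#'   `x`, `y` columns (p >= 2).
#' @return A positive scalar.
#' @export
#' @examples
#' centroid_size(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))) # sqrt(2)
centroid_size <- function(config) {
  pts <- as_xy_matrix(config, "config")
  if (nrow(pts) < 2) abort("centroid size needs at least 2 points")
  centred <- sweep(pts, 2, colMeans(pts))
  cs <- sqrt(sum(centred^2))
  if (cs == 0) abort("all points coincide; centroid size undefined")
  cs
}

# Split a long landmark tibble into an ordered named list of p x 2 matrices.
configs_from_tibble <- function(landmarks) {
  stopifnot(all(c("specimen_id", "point", "x", "y") %in% names(landmarks)))
  ids <- unique(landmarks$specimen_id)
  lapply(setNames(ids, ids), function(id) {
    rec <- landmarks[landmarks$specimen_id == id, ]
    rec <- rec[order(rec$point), ]
    cbind(x = rec$x, y = rec$y)
  })
}

configs_to_tibble <- function(configs) {
  dplyr::bind_rows(lapply(names(configs), function(id) {
    tibble::tibble(
      specimen_id = id, point = seq_len(nrow(configs[[id]])),
      x = configs[[id]][, 1], y = configs[[id]][, 2]
    )
  }))
}

as_config_list <- function(x) {
  if (is.data.frame(x)) {
    configs_from_tibble(x)
  } else if (is.list(x) && !is.data.frame(x)) {
    configs <- lapply(x, as_xy_matrix)
    if (is.null(names(configs))) {
      names(configs) <- sprintf("specimen_%d", seq_along(configs))
    }
    configs
  } else {
    abort("expected a landmark tibble or a list of coordinate matrices")
  }
}

# Optimal rotation matrix aligning centered X onto centered Y.
optimal_rotation <- function(X, Y, allow_reflection = FALSE) {
  s <- svd(crossprod(X, Y))
  R <- s$u %*% t(s$v)
  if (!allow_reflection && det(R) < 0) {
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(s$v)
  }
  R
}

#' Generalized Procrustes analysis
#'
#' Iterative least-squares superimposition of a sample of landmark
#' configurations: translation is removed by centering, size by scaling each
#' configuration to unit centroid size, and rotation by aligning each
#' configuration to the running consensus until the summed squared deviation
#' from the consensus stops decreasing (full Procrustes fit). Reflections
#' are excluded by default because biological specimens have handedness.
#'
#' @param landmarks A long landmark tibble (`specimen_id`, `point`, `x`,
#'   `y`) as returned by [read_tps()], or a (named) list of p x 2 matrices.
#'   All configurations must share landmark count and ordering.
#' @param allow_reflection Permit improper rotations during alignment.
#' @param tol Convergence tolerance on the change in the Procrustes sum of
#'   squares between sweeps.
#' @param max_iter Maximum alignment sweeps.
#' @return An object of class `"aligned_shapes"`: a list with `coords`
#'   (long tibble of Procrustes coordinates), `configs` (named list of
#'   aligned matrices), `consensus` (unit-size mean configuration),
#'   `centroid_sizes` (tibble `specimen_id`, `centroid_size` of the raw
#'   configurations), `rss`, `iterations`, `converged`.
#' @export
gpa <- function(landmarks, allow_reflection = FALSE, tol = 1e-10, max_iter = 100) {
  configs <- as_config_list(landmarks)
  n <- length(configs)
  if (n < 2) abort("GPA needs at least 2 configurations")
  p <- nrow(configs[[1]])
  if (!all(vapply(configs, nrow, 0L) == p)) {
    abort("all configurations must share the same landmark count")
  }
  sizes <- vapply(configs, centroid_size, 0)
  pre <- lapply(configs, function(X) {
    Xc <- sweep(X, 2, colMeans(X))
    Xc / sqrt(sum(Xc^2))
  })
  consensus <- pre[[1]]
  rss_old <- Inf
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    pre <- lapply(pre, function(X) X %*% optimal_rotation(X, consensus, allow_reflection))
    consensus <- Reduce(`+`, pre) / n
    consensus <- consensus / sqrt(sum(consensus^2))
    rss <- sum(vapply(pre, function(X) sum((X - consensus)^2), 0))
    if (abs(rss_old - rss) < tol) {
      converged <- TRUE
      break
    }
    rss_old <- rss
  }
  names(pre) <- names(configs)
  structure(
    list(
      coords = configs_to_tibble(pre),
      configs = pre,
      consensus = consensus,
      centroid_sizes = tibble::tibble(
        specimen_id = names(configs), centroid_size = unname(sizes)
      ),
      rss = rss, iterations = iter, converged = converged
    ),
    class = "aligned_shapes"
  )
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat(sprintf(
    "<aligned_shapes: %d specimens x %d landmarks, Procrustes SS %.6g (%d sweeps)>\n",
    length(x$configs), nrow(x$consensus), x$rss, x$iterations
  ))
  invisible(x)
}

#' @export
tidy.aligned_shapes <- function(x, ...) {
  dplyr::left_join(x$coords, x$centroid_sizes, by = "specimen_id")
}

#' @export
glance.aligned_shapes <- function(x, ...) {
  tibble::tibble(
    n = length(x$configs), p = nrow(x$consensus),
    rss = x$rss, iterations = x$iterations, converged = x$converged
  )
}

#' Procrustes distance between two shapes
#'
#' Square root of the minimal summed squared coordinate difference over
#' rotations, after both configurations are centered and scaled to unit
#' centroid size. Symmetric, zero iff the shapes coincide up to similarity.
#'
#' @param a,b Landmark configurations with matching landmark counts.
#' @param allow_reflection Permit improper rotations.
#' @return A non-negative scalar.
#' @export
procrustes_distance <- function(a, b, allow_reflection = FALSE) {
  A <- as_xy_matrix(a, "a")
  B <- as_xy_matrix(b, "b")
  if (nrow(A) != nrow(B)) abort("landmark counts differ")
  A <- sweep(A, 2, colMeans(A))
  A <- A / sqrt(sum(A^2))
  B <- sweep(B, 2, colMeans(B))
  B <- B / sqrt(sum(B^2))
  R <- optimal_rotation(B, A, allow_reflection)
  sqrt(sum((A - B %*% R)^2))
}

#' Symmetrize a bilaterally paired configuration
#'
#' Averages each bilateral landmark pair with the reflection of its
#' antimere across the body axis, yielding a perfectly symmetric
#' configuration (used for the head centroid size) plus the one-side +
#' midline half configuration used in the shape analysis. The body axis is
#' the total-least-squares line through the midline points; with fewer than
#' two midline points it falls back to the principal axis of the
#' configuration. Midline points are projected onto the axis, which makes
#' the operation idempotent.
#'
#' @param config A p x 2 matrix or `x`/`y` data frame.
#' @param schema A [landmark_schema()] with a `pairs` map.
#' @return A list with `full` (symmetrized p x 2 matrix), `half` (one side
#'   plus midline, in original point order), `half_index` (original indices
#'   of the half rows), and `axis` (`center`, `direction`).
#' @export
symmetrize_bilateral <- function(config, schema) {
  pts <- as_xy_matrix(config, "config")
  if (!inherits(schema, "landmark_schema") || is.null(schema$pairs)) {
    abort("symmetrization requires a schema with a bilateral pair map")
  }
  if (nrow(pts) != length(schema$roles)) {
    abort("configuration size does not match schema")
  }
  pairs <- schema$pairs
  midline <- schema$midline
  if (length(midline) >= 2) {
    ctr <- colMeans(pts[midline, , drop = FALSE])
    cm <- sweep(pts[midline, , drop = FALSE], 2, ctr)
    u <- svd(cm)$v[, 1]
  } else {
    # principal-axis fallback: of the two principal directions, take the
    # one across which reflecting each antimere best matches its partner
    ctr <- colMeans(pts)
    cm <- sweep(pts, 2, ctr)
    V <- svd(cm)$v
    asym <- vapply(1:2, function(k) {
      u <- V[, k]
      refl <- function(z) {
        v <- z - ctr
        ctr + 2 * sum(v * u) * u - v
      }
      sum(vapply(seq_len(nrow(pairs)), function(j) {
        sum((refl(pts[pairs[j, 2], ]) - pts[pairs[j, 1], ])^2)
      }, 0))
    }, 0)
    u <- V[, which.min(asym)]
  }
  u <- u / sqrt(sum(u^2))
  reflect <- function(z) {
    v <- z - ctr
    ctr + 2 * sum(v * u) * u - v
  }
  project <- function(z) {
    v <- z - ctr
    ctr + sum(v * u) * u
  }
  full <- pts
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]
    j <- pairs[k, 2]
    si <- (pts[i, ] + reflect(pts[j, ])) / 2
    full[i, ] <- si
    full[j, ] <- reflect(si)
  }
  for (m in midline) full[m, ] <- project(pts[m, ])
  half_index <- sort(c(midline, pairs[, 1]))
  list(
    full = full,
    half = full[half_index, , drop = FALSE],
    half_index = half_index,
    axis = list(center = ctr, direction = u)
  )
}

#' Mean shape of a set of aligned configurations
#'
#' Coordinate-wise mean, re-scaled to unit centroid size. Inputs are
#' expected to be Procrustes-aligned (e.g. from [gpa()]).
#'
#' @param x An `"aligned_shapes"` object, a landmark tibble, or a list of
#'   aligned matrices.
#' @param specimens Optional character vector restricting to a subset of
#'   specimen ids.
#' @return A p x 2 matrix of unit centroid size.
#' @export
mean_shape <- function(x, specimens = NULL) {
  configs <- if (inherits(x, "aligned_shapes")) x$configs else as_config_list(x)
  if (!is.null(specimens)) {
    missing <- setdiff(specimens, names(configs))
    if (length(missing)) abort(sprintf("unknown specimen(s): %s", paste(missing, collapse = ", ")))
    configs <- configs[specimens]
  }
  if (length(configs) == 0) abort("empty group: no configurations to average")
  m <- Reduce(`+`, configs) / length(configs)
  m <- sweep(m, 2, colMeans(m))
  m / sqrt(sum(m^2))
}

#' Export aligned coordinates as a wide per-specimen table
#'
#' One row per specimen with columns `x1, y1, ..., xp, yp`, the layout
#' consumed by the integration and discrimination stages.
#'
#' @param aligned An `"aligned_shapes"` object.
#' @return A tibble with `specimen_id` plus 2p coordinate columns.
#' @export
aligned_coord_matrix <- function(aligned) {
  stopifnot(inherits(aligned, "aligned_shapes"))
  rows <- lapply(aligned$configs, function(X) as.vector(t(X)))
  m <- do.call(rbind, rows)
  p <- nrow(aligned$consensus)
  colnames(m) <- as.vector(rbind(paste0("x", 1:p), paste0("y", 1:p)))
  dplyr::bind_cols(
    tibble::tibble(specimen_id = names(aligned$configs)),
    tibble::as_tibble(m)
  )
}
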