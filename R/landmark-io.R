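#' Read a TPS landmark file
#'
#' Parses landmark configurations digitized in the TPS dialect written by
#' tpsDig: each record is an `LM=<n>` (or `LM3=<n>`) header followed by `n`
#' whitespace-separated `x y` coordinate lines, optionally followed by
#' `ID=`, `IMAGE=` and `SCALE=` keys. When a `SCALE=` key is present the raw
#' (pixel) coordinates are multiplied by it, so returned coordinates are in
#' calibrated units (mm for our images). The y axis is kept exactly as
#' stored; all downstream statistics are similarity-invariant, so the image
#' convention has no geometric consequence.
#'
#' @param path Path to a TPS file.
#' @return A tibble with one row per landmark and columns `specimen_id`,
#'   `point` (1-based index, TPS convention), `x`, `y`. Record order is
#'   preserved. Per-record metadata (`image`, `scale`) is attached as the
#'   `"tps_meta"` attribute.
#' @seealso [write_tps()], [landmark_schema()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tps")
#' writeLines(c("LM=3", "0 0", "1 0", "0 1", "ID=s1", "SCALE=2.0"), tf)
#' read_tps(tf)
read_tps <- function(path) {
  if (!file.exists(path)) abort(sprintf("TPS file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  recs <- list()
  i <- 1L
  n_lines <- length(lines)
  rec_no <- 0L
  while (i <= n_lines) {
    if (lines[i] == "") {
      i <- i + 1L
      next
    }
    header <- regmatches(lines[i], regexec("^LM[0-9]*=\\s*([0-9]+)\\s*$", lines[i]))[[1]]
    if (length(header) == 0) {
      abort(sprintf("line %d: expected an LM=<n> record header, got '%s'", i, lines[i]))
    }
    rec_no <- rec_no + 1L
    n_pts <- as.integer(header[2])
    coords <- matrix(NA_real_, n_pts, 2)
    i <- i + 1L
    for (k in seq_len(n_pts)) {
      while (i <= n_lines && lines[i] == "") i <- i + 1L
      if (i > n_lines || grepl("^(LM[0-9]*|ID|IMAGE|SCALE)=", lines[i])) {
        abort(sprintf(
          "record %d: LM=%d declared but only %d coordinate line(s) found",
          rec_no, n_pts, k - 1L
        ))
      }
      xy <- suppressWarnings(as.numeric(strsplit(lines[i], "\\s+")[[1]]))
      if (length(xy) != 2 || anyNA(xy)) {
        abort(sprintf("line %d: non-numeric or malformed coordinate '%s'", i, lines[i]))
      }
      coords[k, ] <- xy
      i <- i + 1L
    }
    id <- NA_character_
    image <- NA_character_
    scale <- NA_real_
    while (i <= n_lines && grepl("^(ID|IMAGE|SCALE)=", lines[i])) {
      key <- sub("=.*$", "", lines[i])
      val <- sub("^[A-Z]+=", "", lines[i])
      if (key == "ID") id <- val
      if (key == "IMAGE") image <- val
      if (key == "SCALE") {
        scale <- suppressWarnings(as.numeric(val))
        if (is.na(scale)) abort(sprintf("line %d: non-numeric SCALE value", i))
      }
      i <- i + 1L
    }
    if (!is.na(scale)) coords <- coords * scale
    if (is.na(id)) id <- sprintf("specimen_%d", rec_no)
    recs[[rec_no]] <- tibble::tibble(
      specimen_id = id, point = seq_len(n_pts),
      x = coords[, 1], y = coords[, 2]
    )
    attr(recs[[rec_no]], "meta") <- tibble::tibble(
      specimen_id = id, image = image, scale = scale
    )
  }
  if (length(recs) == 0) abort(sprintf("no TPS records found in %s", path))
  meta <- dplyr::bind_rows(lapply(recs, attr, "meta"))
  out <- dplyr::bind_rows(recs)
  attr(out, "tps_meta") <- meta
  out
}

#' Write landmark configurations to a TPS file
#'
#' Inverse of [read_tps()]: coordinates are written as stored (no scale is
#' applied or emitted), so `read_tps(write_tps(x, f))` reproduces `x`'s
#' coordinates exactly.
#'
#' @param landmarks Tibble with columns `specimen_id`, `point`, `x`, `y`.
#' @param path Output path.
#' @param digits Significant digits written (default 15, round-trip safe).
#' @return `path`, invisibly.
#' @export
write_tps <- function(landmarks, path, digits = 15) {
  stopifnot(all(c("specimen_id", "point", "x", "y") %in% names(landmarks)))
  ids <- unique(landmarks$specimen_id)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in ids) {
    rec <- landmarks[landmarks$specimen_id == id, ]
    rec <- rec[order(rec$point), ]
    writeLines(sprintf("LM=%d", nrow(rec)), con)
    writeLines(
      paste(
        formatC(rec$x, digits = digits, format = "g"),
        formatC(rec$y, digits = digits, format = "g")
      ),
      con
    )
    writeLines(sprintf("ID=%s", id), con)
  }
  invisible(path)
}

#' Resample a digitized curve into equally spaced semilandmarks
#'
#' Places `n_semi` points at equal arc-length intervals strictly between the
#' endpoints of a polyline, the convention used for the outline semilandmarks
#' ("spaced at equal intervals between landmarks"). The result is stable
#' under refinement of the input polyline: densifying the curve without
#' changing its geometry leaves the semilandmarks unchanged.
#'
#' @param curve_points Polyline vertices: a matrix or data frame with two
#'   columns (or `x`/`y` columns), at least 2 rows.
#' @param n_semi Number of semilandmarks to place (>= 0).
#' @return A tibble with `n_semi` rows and columns `x`, `y`.
#' @export
#' @examples
#' resample_semilandmarks(rbind(c(0, 0), c(0, 3)), 2)
resample_semilandmarks <- function(curve_points, n_semi) {
  pts <- as_xy_matrix(curve_points, "curve_points")
  if (nrow(pts) < 2) abort("curve must have at least 2 points")
  if (n_semi < 0) abort("n_semi must be >= 0")
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  total <- sum(seg)
  if (total <= 0) abort("degenerate zero-length curve")
  if (n_semi == 0) {
    return(tibble::tibble(x = numeric(0), y = numeric(0)))
  }
  cum <- c(0, cumsum(seg))
  targets <- total * seq_len(n_semi) / (n_semi + 1)
  out <- matrix(NA_real_, n_semi, 2)
  for (k in seq_len(n_semi)) {
    j <- findInterval(targets[k], cum, rightmost.closed = TRUE)
    j <- min(j, nrow(pts) - 1L)
    frac <- if (seg[j] > 0) (targets[k] - cum[j]) / seg[j] else 0
    out[k, ] <- pts[j, ] + frac * (pts[j + 1, ] - pts[j, ])
  }
  tibble::tibble(x = out[, 1], y = out[, 2])
}

# Landmark schemas ------------------------------------------------------------

#' Define a landmark schema
#'
#' A schema records, for one digitizing view, which points are fixed
#' landmarks vs outline semilandmarks, which point pairs are bilaterally
#' homologous (dorsal view), and which points sit on the midline. The
#' photographed configurations themselves never carry this information, so
#' it travels as a configuration artifact alongside the TPS data. Indices
#' are 1-based, matching TPS convention.
#'
#' @param roles Character vector, one of `"fixed"`/`"semi"` per point.
#' @param pairs Two-column matrix (or list of length-2 vectors) of bilateral
#'   (left, right) point index pairs, or `NULL` for views without object
#'   symmetry.
#' @param midline Integer indices of unpaired midline points.
#' @param view `"dorsal"` or `"lateral"`.
#' @return An object of class `"landmark_schema"`.
#' @export
landmark_schema <- function(roles, pairs = NULL, midline = integer(), view = c("dorsal", "lateral")) {
  view <- match.arg(view)
  roles <- match.arg(roles, c("fixed", "semi"), several.ok = TRUE)
  n <- length(roles)
  if (n < 3) abort("a schema needs at least 3 points")
  if (!is.null(pairs)) {
    if (is.list(pairs)) pairs <- do.call(rbind, pairs)
    pairs <- matrix(as.integer(pairs), ncol = 2)
    idx <- c(pairs, midline)
    if (any(idx < 1 | idx > n)) abort("pair/midline indices out of range")
    if (anyDuplicated(idx)) abort("pair and midline indices must be disjoint")
  } else if (length(midline)) {
    abort("midline indices require a paired (dorsal) schema")
  }
  structure(
    list(roles = roles, pairs = pairs, midline = as.integer(midline), view = view),
    class = "landmark_schema"
  )
}

#' @export
print.landmark_schema <- function(x, ...) {
  cat(sprintf(
    "<landmark_schema: %s view, %d points (%d fixed, %d semi), %d pairs, %d midline>\n",
    x$view, length(x$roles), sum(x$roles == "fixed"), sum(x$roles == "semi"),
    if (is.null(x$pairs)) 0L else nrow(x$pairs), length(x$midline)
  ))
  invisible(x)
}

#' Default dorsal and lateral landmark schemas
#'
#' The default dorsal head schema has 9 bilateral pairs of fixed landmarks,
#' 1 fixed midline point (snout tip) and 10 bilateral pairs of outline
#' semilandmarks (39 points). The default lateral body schema has 8 fixed
#' landmarks and 12 semilandmarks (20 points, no object symmetry). These
#' counts are a documented fixture choice: published figures of such
#' configurations are schematic and do not pin exact counts, and none of the
#' downstream statistics depend on them.
#'
#' @return A `"landmark_schema"`.
#' @export
default_dorsal_schema <- function() {
  # point 1 = snout tip (midline); pairs listed (left, right)
  roles <- c("fixed", rep("fixed", 18), rep("semi", 20))
  pairs <- cbind(seq(2, 38, by = 2), seq(3, 39, by = 2))
  landmark_schema(roles, pairs = pairs, midline = 1L, view = "dorsal")
}

#' @rdname default_dorsal_schema
#' @export
default_lateral_schema <- function() {
  landmark_schema(c(rep("fixed", 8), rep("semi", 12)), view = "lateral")
}
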