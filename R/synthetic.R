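#' Generator parameters for a synthetic dimorphic study
#'
#' Defaults emulate the rearing experiment the analysis is built for: 10
#' high-density tanks of 30 larvae plus 30 solitary larvae; 1-9 victims
#' per tank; 1-6 cannibals per tank positively coupled with the victim
#' count. High-density specimens follow a shared size-shape integration
#' rule (shape score linear in latent size with negative slope, so large
#' specimens are cannibal-like), while solitary specimens draw size and
#' shape independently. Cannibals gain latent size in proportion to the
#' victims they consumed; victims are partitioned among a tank's cannibals
#' by a Dirichlet-like scheme whose `concentration` spans egalitarian
#' (large values) to winner-takes-all (small values), mirroring the
#' exploitation models that the selection stage distinguishes.
#'
#' @param n_tanks,n_per_tank,n_solitary Experimental layout.
#' @param victim_range Integer support of the per-tank victim draw.
#' @param cannibal_prob Binomial rate coupling extra cannibals to victims:
#'   `x1 = 1 + Binomial(x2 - 1, cannibal_prob)` (capped at survivors).
#' @param concentration Gamma shape of the victim-partition weights.
#' @param integration_slope,integration_intercept,integration_resid_sd The
#'   high-density size-shape rule `shape = intercept + slope * size + eps`.
#' @param size_sd Baseline latent size SD (all survivors).
#' @param size_gain Latent size increment per victim consumed.
#' @param solitary_size_sd,solitary_shape_sd Independent solitary draws
#'   (zero means, zero correlation).
#' @param scale_per_unit Log-scale body size change per latent size unit.
#' @param deform_gain,fin_gain Amplitude (mm) of the dorsal head-widening
#'   and lateral fin-depth deformation per shape-score unit.
#' @param landmark_noise_sd Isotropic digitizing noise SD (mm).
#' @param stomach_prob,visual_prob Probabilities that a cannibal carries
#'   stomach evidence / is visually identified (visual requires >= 2
#'   victims consumed).
#' @return A list of class `"generator_params"`.
#' @export
generator_params <- function(n_tanks = 10, n_per_tank = 30, n_solitary = 30,
                             victim_range = 1:9, cannibal_prob = 0.35,
                             concentration = 0.5,
                             integration_slope = -0.5,
                             integration_intercept = 0,
                             integration_resid_sd = 0.25,
                             size_sd = 0.5, size_gain = 0.35,
                             solitary_size_sd = 0.5, solitary_shape_sd = 0.25,
                             scale_per_unit = 0.08,
                             deform_gain = 0.15, fin_gain = 0.3,
                             landmark_noise_sd = 0.02,
                             stomach_prob = 0.4, visual_prob = 0.7) {
  p <- as.list(environment())
  stopifnot(
    p$n_tanks >= 1, p$n_per_tank >= 3, p$n_solitary >= 3,
    all(p$victim_range >= 0), p$concentration > 0,
    p$integration_resid_sd > 0, p$size_sd > 0, p$solitary_size_sd > 0,
    p$solitary_shape_sd > 0, p$landmark_noise_sd >= 0
  )
  structure(p, class = "generator_params")
}

# Landmark templates -----------------------------------------------------

# Dorsal head template matching default_dorsal_schema(): snout tip on the
# midline plus 19 bilateral pairs on a smooth head outline (axial axis =
# y, anterior = +y). Units are mm for a typical larva head.
dorsal_template <- function() {
  half_width <- function(t) 2 * sqrt(pmax(1 - t^2, 0)) + 0.15 * (1 - t)
  pts <- matrix(NA_real_, 39, 2)
  pts[1, ] <- c(0, 3) # snout tip
  t_fixed <- seq(0.85, -0.85, length.out = 9)
  t_semi <- seq(0.95, -0.95, length.out = 10)
  for (k in 1:9) {
    y <- 3 * t_fixed[k]
    w <- half_width(t_fixed[k])
    pts[2 * k, ] <- c(-w, y)
    pts[2 * k + 1, ] <- c(w, y)
  }
  for (k in 1:10) {
    y <- 3 * t_semi[k]
    w <- half_width(t_semi[k]) * 0.97
    pts[18 + 2 * k, ] <- c(-w, y)
    pts[19 + 2 * k, ] <- c(w, y)
  }
  pts
}

# Project a deformation vector orthogonal to the centered template so the
# deformation is centroid-size-neutral to first order (the gradient of
# centroid size is the centered configuration itself): pure shape change,
# no size change, keeping the size and shape channels independent.
cs_neutral <- function(v, tpl) {
  ctr <- sweep(tpl, 2, colMeans(tpl))
  v <- sweep(v, 2, colMeans(v)) # translation-neutral
  v <- v - ctr * sum(v * ctr) / sum(ctr^2)
  v / sqrt(sum(v^2))
}

# Anterior head widening: displaces paired points outward with a weight
# that grows toward the snout, morphing a trigonal outline toward a
# tetragonal one. Unit norm, centroid-size-neutral.
dorsal_widen_vector <- function() {
  tpl <- dorsal_template()
  v <- matrix(0, 39, 2)
  w <- pmax((tpl[, 2] + 3) / 6, 0)^2
  v[, 1] <- sign(tpl[, 1]) * w
  cs_neutral(v, tpl)
}

# Lateral body template matching default_lateral_schema(): 8 fixed
# landmarks (snout, eye, gill, vent, tail, jaw corner, plus fin base
# points) and 12 semilandmarks along the dorsal fin outline. Axial axis =
# x (anterior = 0), body length 12 mm.
lateral_template <- function() {
  fixed <- rbind(
    c(0, 0.6), # snout tip
    c(0.9, 1.0), # eye
    c(2.0, 0.2), # jaw corner / gill (ventral)
    c(2.6, 1.3), # head-trunk boundary, dorsal
    c(9.0, 0.2), # vent (ventral)
    c(12, 0.7), # tail point
    c(3.2, 0.1), # limb base, ventral
    c(6.0, 0.0) # mid ventral
  )
  xs <- seq(3.0, 11.2, length.out = 12)
  depth <- 1.4 + 1.1 * sin(pi * pmin(pmax((xs - 2.6) / 8.6, 0), 1))
  rbind(fixed, cbind(xs, depth))
}

# Dorsal-fin depth: vertical displacement of the fin outline
# semilandmarks, peaked mid-body. Unit norm, centroid-size-neutral.
lateral_fin_vector <- function() {
  tpl <- lateral_template()
  v <- matrix(0, nrow(tpl), 2)
  xs <- tpl[9:20, 1]
  v[9:20, 2] <- sin(pi * pmin(pmax((xs - 2.6) / 8.6, 0), 1))
  cs_neutral(v, tpl)
}

#' Body dimensions measured from a specimen's landmark configurations
#'
#' Re-derives the measurement record geometrically from the landmark
#' coordinates: the head widths (HW, JW1, JW2, EW) are distances between
#' specific bilateral pairs of the dorsal configuration, the head lengths
#' (HL1-HL3) are snout-tip-to-pair-midpoint distances, and SVL is the
#' snout-to-vent distance on the lateral configuration. This is the same
#' function the generator uses to emit measurements, so emitted records
#' always agree with the landmarks.
#'
#' @param dorsal,lateral p x 2 coordinate matrices laid out as the default
#'   schemas.
#' @return A one-row tibble of the eight dimensions (mm).
#' @export
measure_configuration <- function(dorsal, lateral) {
  dorsal <- as_xy_matrix(dorsal, "dorsal")
  lateral <- as_xy_matrix(lateral, "lateral")
  pair_width <- function(k) sqrt(sum((dorsal[2 * k, ] - dorsal[2 * k + 1, ])^2))
  pair_mid <- function(k) (dorsal[2 * k, ] + dorsal[2 * k + 1, ]) / 2
  snout <- dorsal[1, ]
  tibble::tibble(
    HW = pair_width(5), # widest station
    JW1 = pair_width(1), # anterior jaw
    JW2 = pair_width(2),
    EW = pair_width(3), # eye width
    HL1 = sqrt(sum((snout - pair_mid(3))^2)),
    HL2 = sqrt(sum((snout - pair_mid(6))^2)),
    HL3 = sqrt(sum((snout - pair_mid(9))^2)),
    SVL = sqrt(sum((lateral[1, ] - lateral[5, ])^2))
  )
}

#' Generate one synthetic specimen
#'
#' Deforms the dorsal and lateral templates by the specimen's shape score
#' (anterior head widening for cannibal-like shapes, dorsal fin depth for
#' noncannibal-like shapes), scales by the latent size, adds isotropic
#' landmark noise, and derives the measurement record from the resulting
#' coordinates. Draws from the current RNG stream.
#'
#' @param category `"Cannibal"`, `"NonCannibal"` or `"Solitary"`.
#' @param s Latent size (log-scale units around 0).
#' @param params A [generator_params()] list.
#' @param shape Optional shape score; by default drawn from the category's
#'   rule (high-density integration line, or the independent solitary
#'   cloud).
#' @return A list with `dorsal`, `lateral` (coordinate matrices),
#'   `measurements` (one-row tibble), and `shape` (the latent shape used).
#' @export
generate_specimen <- function(category, s, params = generator_params(), shape = NULL) {
  if (!category %in% c("Cannibal", "NonCannibal", "Solitary")) {
    abort(sprintf("invalid category: %s", category))
  }
  if (is.null(shape)) {
    shape <- if (category == "Solitary") {
      rnorm(1, 0, params$solitary_shape_sd)
    } else {
      params$integration_intercept + params$integration_slope * s +
        rnorm(1, 0, params$integration_resid_sd)
    }
  }
  scale <- exp(params$scale_per_unit * s)
  # low shape score = cannibal-like: widened anterior head, shallow fin
  dorsal <- (dorsal_template() - shape * params$deform_gain * dorsal_widen_vector() * 39) * scale
  lateral <- (lateral_template() + shape * params$fin_gain * lateral_fin_vector() * 20) * scale
  if (params$landmark_noise_sd > 0) {
    dorsal <- dorsal + matrix(rnorm(length(dorsal), 0, params$landmark_noise_sd), ncol = 2)
    lateral <- lateral + matrix(rnorm(length(lateral), 0, params$landmark_noise_sd), ncol = 2)
  }
  list(
    dorsal = dorsal, lateral = lateral,
    measurements = measure_configuration(dorsal, lateral),
    shape = shape
  )
}

#' Generate a complete synthetic study
#'
#' Draws the tank-level census process (victims, cannibals, victim
#' partition among cannibals), the specimen-level latent sizes and shapes
#' under the high-density integration rule or the solitary cloud, and the
#' landmark configurations and measurement records for every survivor.
#' Fully reproducible from `seed`.
#'
#' @param params A [generator_params()] list.
#' @param seed Integer seed.
#' @return An object of class `"synthetic_study"`: a list with
#'   `landmarks` (long tibble with `view` column), `measurements`,
#'   `census`, `truth` (per-specimen latent scores, labels and victims
#'   consumed), `params`, `seed`.
#' @export
generate_study <- function(params = generator_params(), seed = 1) {
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  landmarks <- list()
  meas <- list()
  truth <- list()
  census <- list()
  add_specimen <- function(id, tank, category, s, consumed) {
    sp <- generate_specimen(category, s, params)
    landmarks[[length(landmarks) + 1]] <<- dplyr::bind_rows(
      tibble::tibble(
        specimen_id = id, view = "dorsal", point = seq_len(nrow(sp$dorsal)),
        x = sp$dorsal[, 1], y = sp$dorsal[, 2]
      ),
      tibble::tibble(
        specimen_id = id, view = "lateral", point = seq_len(nrow(sp$lateral)),
        x = sp$lateral[, 1], y = sp$lateral[, 2]
      )
    )
    stomach <- category == "Cannibal" && consumed >= 1 && runif(1) < params$stomach_prob
    visual <- category == "Cannibal" && consumed >= 2 && runif(1) < params$visual_prob
    meas[[length(meas) + 1]] <<- dplyr::bind_cols(
      tibble::tibble(specimen_id = id, tank_id = tank),
      sp$measurements,
      tibble::tibble(stomach_conspecific = stomach, visual_cannibal = visual)
    )
    truth[[length(truth) + 1]] <<- tibble::tibble(
      specimen_id = id, tank_id = tank, category = category,
      latent_size = s, latent_shape = sp$shape, victims_consumed = consumed
    )
  }
  for (t in seq_len(params$n_tanks)) {
    tank <- sprintf("g%d", t)
    repeat {
      x2 <- sample(params$victim_range, 1)
      survivors <- params$n_per_tank - x2
      x1 <- 1 + stats::rbinom(1, max(x2 - 1, 0), params$cannibal_prob)
      if (x1 <= survivors && survivors >= 3) break
      warn(sprintf("tank %s: infeasible counts drawn, resampling", tank))
    }
    # partition victims among cannibals: egalitarian <-> exclusive
    wts <- stats::rgamma(x1, shape = params$concentration)
    if (sum(wts) == 0) wts <- rep(1, x1)
    consumed <- as.vector(stats::rmultinom(1, x2, wts / sum(wts)))
    consumed <- sort(consumed, decreasing = TRUE)
    for (i in seq_len(survivors)) {
      cat_i <- if (i <= x1) "Cannibal" else "NonCannibal"
      cons_i <- if (i <= x1) consumed[i] else 0
      s <- rnorm(1, 0, params$size_sd) + params$size_gain * cons_i
      add_specimen(sprintf("%s_s%02d", tank, i), tank, cat_i, s, cons_i)
    }
    census[[t]] <- tibble::tibble(
      tank_id = tank, n_initial = params$n_per_tank,
      n_survivors = survivors, n_cannibals = x1
    )
  }
  for (i in seq_len(params$n_solitary)) {
    s <- rnorm(1, 0, params$solitary_size_sd)
    add_specimen(sprintf("sol_s%02d", i), "sol", "Solitary", s, 0)
  }
  structure(
    list(
      landmarks = dplyr::bind_rows(landmarks),
      measurements = dplyr::bind_rows(meas),
      census = validate_census(dplyr::bind_rows(census)),
      truth = dplyr::bind_rows(truth),
      params = params, seed = seed
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study: %d tanks, %d specimens, seed %d>\n",
    nrow(x$census), nrow(x$truth), x$seed
  ))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits the TPS files (one per view), the measurement and census CSVs in
#' the package's dialects, plus a JSON manifest recording the generator
#' parameters and seed.
#'
#' @param study A `"synthetic_study"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (v in c("dorsal", "lateral")) {
    write_tps(
      study$landmarks[study$landmarks$view == v, ],
      file.path(dir, sprintf("landmarks_%s.tps", v))
    )
  }
  write_measurements_csv(study$measurements, file.path(dir, "measurements.csv"))
  write_census_csv(study$census, file.path(dir, "census.csv"))
  readr::write_csv(study$truth, file.path(dir, "truth.csv"))
  manifest <- c(
    list(seed = study$seed),
    lapply(unclass(study$params), unclass)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
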