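#' Per-specimen integration scores from both landmark views
#'
#' The score-construction backbone of the analysis. Dorsal head
#' configurations are symmetrized about the body axis (the full symmetric
#' configuration, at raw scale, gives the head centroid size `HeadCS`; one
#' side plus the midline enters the shape analysis), both views are
#' Procrustes-superimposed, and a two-block PLS of the dorsal vs lateral
#' Procrustes coordinates yields the paired `PLS1_dorsal` / `PLS1_lateral`
#' shape scores. PC1 of that score plane is the single-dimension shape
#' axis `PC1_shape`; PC1 of the (SVL, HeadCS) plane is the size axis
#' `PC1_size`. Both plane PCAs are computed on raw (unstandardized) score
#' pairs, i.e. they are major-axis regression lines of the planes.
#'
#' Sign conventions: `PC1_size` is oriented to increase with HeadCS;
#' `PC1_shape` is oriented so cannibal-labelled specimens score low (via
#' `category`), falling back to a negative correlation with HeadCS (large
#' specimens are cannibal-like) when no labels are given.
#'
#' @param landmarks Long landmark tibble with columns `specimen_id`,
#'   `view` (`"dorsal"`/`"lateral"`), `point`, `x`, `y`.
#' @param meta Per-specimen tibble with `specimen_id`, `SVL`, and
#'   optionally `category` and `population` (tank id).
#' @param dorsal_schema,lateral_schema Landmark schemas.
#' @param n_perm Permutations for the PLS axis-1 correlation test.
#' @param seed Optional seed for the permutation test.
#' @return A tibble with one row per specimen: `specimen_id`,
#'   `PLS1_dorsal`, `PLS1_lateral`, `PC1_shape`, `PC2_shape`, `SVL`,
#'   `HeadCS`, `PC1_size`, `PC2_size`, plus `category` / `population`
#'   when given. The fitted `pls_fit`, the two `pca_axes` and the two
#'   `aligned_shapes` objects are attached as the `"fits"` attribute.
#' @export
integration_scores <- function(landmarks, meta,
                               dorsal_schema = default_dorsal_schema(),
                               lateral_schema = default_lateral_schema(),
                               n_perm = 0, seed = NULL) {
  stopifnot(all(c("specimen_id", "view", "point", "x", "y") %in% names(landmarks)))
  stopifnot(all(c("specimen_id", "SVL") %in% names(meta)))
  dorsal <- configs_from_tibble(landmarks[landmarks$view == "dorsal", ])
  lateral <- configs_from_tibble(landmarks[landmarks$view == "lateral", ])
  ids <- intersect(intersect(names(dorsal), names(lateral)), meta$specimen_id)
  if (length(ids) < 3) abort("need at least 3 specimens present in both views and meta")
  dorsal <- dorsal[ids]
  lateral <- lateral[ids]
  meta <- meta[match(ids, meta$specimen_id), ]
  sym <- lapply(dorsal, symmetrize_bilateral, schema = dorsal_schema)
  head_cs <- vapply(sym, function(s) centroid_size(s$full), 0)
  halves <- lapply(sym, `[[`, "half")
  aligned_dorsal <- gpa(halves)
  aligned_lateral <- gpa(lateral)
  Xd <- as.matrix(aligned_coord_matrix(aligned_dorsal)[, -1])
  Xl <- as.matrix(aligned_coord_matrix(aligned_lateral)[, -1])
  pls <- two_block_pls(Xd, Xl, n_perm = n_perm, seed = seed)
  plane <- cbind(PLS1_dorsal = pls$scores_a[, 1], PLS1_lateral = pls$scores_b[, 1])
  shape_ref <- if ("category" %in% names(meta)) {
    as.numeric(meta$category == "Cannibal")
  } else {
    head_cs
  }
  shape_pca <- pca_scores(plane, orient_by = shape_ref, orient_sign = -1)
  size_pca <- pca_scores(
    cbind(SVL = meta$SVL, HeadCS = head_cs),
    orient_by = head_cs, orient_sign = 1
  )
  out <- tibble::tibble(
    specimen_id = ids,
    PLS1_dorsal = plane[, 1], PLS1_lateral = plane[, 2],
    PC1_shape = shape_pca$scores[, 1], PC2_shape = shape_pca$scores[, 2],
    SVL = meta$SVL, HeadCS = unname(head_cs),
    PC1_size = size_pca$scores[, 1], PC2_size = size_pca$scores[, 2]
  )
  if ("category" %in% names(meta)) out$category <- meta$category
  if ("population" %in% names(meta)) out$population <- meta$population
  attr(out, "fits") <- list(
    pls = pls, shape_pca = shape_pca, size_pca = size_pca,
    aligned_dorsal = aligned_dorsal, aligned_lateral = aligned_lateral
  )
  out
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates a full run from raw inputs to report tables. Three input
#' modes are supported, in decreasing order of precedence:
#'
#' * `summaries_csv`: a population-summary table (`population`, `x1`,
#'   `x2`, `y1`, `y2`, `y3`) — runs only the census stages
#'   (correlation suite, census SMA line, Akaike-weight tables if
#'   `aic_tables` is supplied).
#' * `generator`: a list with `params` ([generator_params()]) and `seed` —
#'   generates a synthetic study and analyses it end to end.
#' * `input`: a list of file paths `dorsal_tps`, `lateral_tps`,
#'   `measurements_csv`, `census_csv`.
#'
#' All stage outputs are written to `out_dir` as CSV plus a `summary.json`
#' and a `manifest.json` recording seeds, stage timings and input mode.
#'
#' @param config A list: `out_dir` (required), `seed` (default 1),
#'   `n_perm` (default 999, minimum 99), one input mode as above, and
#'   optionally `stages` (subset of `"integrate"`, `"populations"`,
#'   `"models"`, `"screen"`; census-suite and SMA always run once
#'   population summaries exist) and `aic_tables` (named list of numeric
#'   AIC vectors to re-weight).
#' @return Invisibly, a named list of the stage results.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) abort("config$out_dir is required")
  seed <- config$seed %||% 1L
  n_perm <- config$n_perm %||% 999L
  if (n_perm < 99) abort("n_perm must be at least 99")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  results <- list()
  log_stage <- function(stage) {
    message(sprintf(
      "[%s] stage=%s elapsed=%.2fs seed=%d",
      format(Sys.time(), "%H:%M:%S"), stage,
      as.numeric(difftime(Sys.time(), t0, units = "secs")), seed
    ))
  }
  stages <- config$stages %||% c("integrate", "populations", "models", "screen")

  summaries <- NULL
  if (!is.null(config$summaries_csv)) {
    if (!file.exists(config$summaries_csv)) {
      abort(sprintf("input file not found: %s", config$summaries_csv))
    }
    summaries <- readr::read_csv(config$summaries_csv, show_col_types = FALSE)
  } else {
    if (!is.null(config$generator)) {
      study <- generate_study(
        params = config$generator$params %||% generator_params(),
        seed = config$generator$seed %||% seed
      )
      landmarks <- study$landmarks
      measurements <- study$measurements
      census <- study$census
    } else if (!is.null(config$input)) {
      paths <- config$input
      for (p in unlist(paths)) {
        if (!file.exists(p)) abort(sprintf("input file not found: %s", p))
      }
      dorsal <- read_tps(paths$dorsal_tps)
      dorsal$view <- "dorsal"
      lateral <- read_tps(paths$lateral_tps)
      lateral$view <- "lateral"
      landmarks <- dplyr::bind_rows(dorsal, lateral)
      measurements <- read_measurements_csv(paths$measurements_csv)
      census <- read_census_csv(paths$census_csv)
    } else {
      abort("config must provide summaries_csv, generator, or input")
    }
    if (!"tank_id" %in% names(measurements)) {
      abort("measurements must carry a tank_id column to assign populations")
    }

    screen <- screen_population(measurements)
    results$screen <- screen
    readr::write_csv(screen, file.path(config$out_dir, "screen.csv"))
    log_stage("screen")

    in_tank <- measurements$tank_id %in% census$tank_id
    category <- ifelse(
      !in_tank, "Solitary",
      ifelse(screen$label[match(measurements$specimen_id, screen$specimen_id)] == "cannibal",
        "Cannibal", "NonCannibal"
      )
    )
    meta <- tibble::tibble(
      specimen_id = measurements$specimen_id,
      SVL = measurements$SVL,
      category = category,
      population = ifelse(in_tank, measurements$tank_id, "sol")
    )

    if ("integrate" %in% stages) {
      scores <- integration_scores(landmarks, meta, n_perm = n_perm, seed = seed)
      results$scores <- scores
      readr::write_csv(scores, file.path(config$out_dir, "scores.csv"))
      fits <- attr(scores, "fits")
      results$integration <- tibble::tibble(
        statistic = c("RV(dorsal,lateral)", "r_PLS1", "pct_sq_cov_1", "pct_var_PC1_shape", "pct_var_PC1_size"),
        value = c(
          escoufier_rv(
            as.matrix(aligned_coord_matrix(fits$aligned_dorsal)[, -1]),
            as.matrix(aligned_coord_matrix(fits$aligned_lateral)[, -1])
          ),
          fits$pls$r_pls1, fits$pls$pct_sq_cov[1],
          fits$shape_pca$pct_variance[1], fits$size_pca$pct_variance[1]
        )
      )
      readr::write_csv(results$integration, file.path(config$out_dir, "integration.csv"))
      log_stage("integrate")

      if ("populations" %in% stages) {
        summaries <- population_distribution_stats(scores, census)
        results$population_stats <- summaries
        readr::write_csv(summaries, file.path(config$out_dir, "population_stats.csv"))
        for (resp in c("PC1_size", "PC1_shape")) {
          nc <- scores[scores$category != "Cannibal", ]
          vic <- ifelse(nc$population == "sol", 0L,
            census$n_victims[match(nc$population, census$tank_id)]
          )
          av <- anova_planned_contrasts(
            tibble::tibble(v = nc[[resp]], g = nc$population, w = vic), v, g, w
          )
          results[[paste0("anova_", resp)]] <- av
          readr::write_csv(tidy(av), file.path(config$out_dir, sprintf("anova_%s.csv", resp)))
        }
        log_stage("populations")
      }

      if ("models" %in% stages && "populations" %in% stages) {
        largest <- largest_cannibal_scores(scores)
        ord <- match(census$tank_id, largest$population)
        has_cb <- !is.na(ord) # tanks where the screen found a cannibal
        for (resp in c("PC1_size", "PC1_shape")) {
          growth_x2 <- unname(c(0, census$n_victims[has_cb]))
          growth_y <- unname(c(
            mean(scores[[resp]][scores$category == "Solitary"]),
            largest[[resp]][ord[has_cb]]
          ))
          results[[paste0("growth_", resp)]] <- compare_growth_models(growth_x2, growth_y)
          results[[paste0("models_", resp)]] <- select_largest_cannibal_models(
            census[has_cb, ], unname(largest[[resp]][ord[has_cb]])
          )
          readr::write_csv(
            dplyr::select(tidy(results[[paste0("models_", resp)]]), -"coefficients"),
            file.path(config$out_dir, sprintf("model_selection_%s.csv", resp))
          )
        }
        log_stage("models")
      }
    }
  }

  if (!is.null(summaries)) {
    suite <- census_correlation_suite(summaries, n_perm = n_perm, seed = seed)
    results$census_suite <- suite
    readr::write_csv(suite, file.path(config$out_dir, "census_suite.csv"))
    sma <- tidy(sma_fit(summaries, x1, x2))
    results$census_sma <- sma
    readr::write_csv(sma, file.path(config$out_dir, "census_sma.csv"))
    log_stage("census-suite")
  }

  if (!is.null(config$aic_tables)) {
    wtabs <- dplyr::bind_rows(lapply(names(config$aic_tables), function(nm) {
      dplyr::bind_cols(tibble::tibble(table = nm), akaike_weights(config$aic_tables[[nm]]))
    }))
    results$akaike_weights <- wtabs
    readr::write_csv(wtabs, file.path(config$out_dir, "akaike_weights.csv"))
    log_stage("weights")
  }

  summary_json <- lapply(results, function(r) {
    if (inherits(r, "model_comparison")) {
      dplyr::select(tidy(r), -"coefficients")
    } else if (inherits(r, "contrast_anova")) {
      tidy(r)
    } else if (is.data.frame(r)) {
      r
    } else {
      NULL
    }
  })
  jsonlite::write_json(
    summary_json[!vapply(summary_json, is.null, TRUE)],
    file.path(config$out_dir, "summary.json"),
    auto_unbox = TRUE, digits = 12
  )
  jsonlite::write_json(
    list(
      package_version = as.character(utils::packageVersion("cannorm")),
      seed = seed, n_perm = n_perm,
      mode = if (!is.null(config$summaries_csv)) {
        "summaries"
      } else if (!is.null(config$generator)) "generator" else "files",
      elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ),
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE
  )
  invisible(results)
}

#' Published AIC columns of the model-comparison tables
#'
#' The printed AIC values of the two worked-example model comparisons: the
#' asymptotic-vs-power growth-form comparison for cannibal size scores,
#' and the six exploitation/interference models for the largest cannibal's
#' size score. Used to exercise the Akaike-weight arithmetic against
#' published weights.
#'
#' @return A tibble with columns `table`, `model`, `k`, `aic`.
#' @export
hynobius_aic_tables <- function() {
  path <- system.file("extdata", "hynobius_aic_tables.csv", package = "cannorm")
  if (path == "") path <- file.path("inst", "extdata", "hynobius_aic_tables.csv")
  readr::read_csv(path, show_col_types = FALSE)
}
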