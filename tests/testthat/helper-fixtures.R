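# Shared fixture builders. All randomness uses the caller's seed via
# set.seed() inside the tests.

# A random p-point configuration with non-degenerate spread.
random_config <- function(p = 8) {
  matrix(rnorm(2 * p), p, 2)
}

# Apply a similarity transform (rotation by angle, scaling, translation).
similarity_transform <- function(X, angle = 0, scale = 1, shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(scale * X %*% R, 2, shift, `+`)
}

# Brute-force Procrustes distance by a two-stage rotation-angle grid
# search (coarse grid, then 1e-5-resolution refinement around the best
# angle). Independent of optimal_rotation()'s SVD path.
grid_procrustes_distance <- function(A, B) {
  pre <- function(X) {
    X <- sweep(X, 2, colMeans(X))
    X / sqrt(sum(X^2))
  }
  A <- pre(A)
  B <- pre(B)
  d_at <- function(theta) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    sqrt(sum((A - B %*% R)^2))
  }
  coarse <- seq(0, 2 * pi, by = 1e-3)
  best <- coarse[which.min(vapply(coarse, d_at, 0))]
  fine <- seq(best - 2e-3, best + 2e-3, by = 1e-5)
  min(vapply(fine, d_at, 0))
}

# Two-morph measurement table: cluster separation `delta` in units of the
# within-cluster SD on every dimension, a fraction of cannibals carrying
# seed flags. Returns the table plus the true labels.
dimorphic_measurements <- function(n = 100, prop_cannibal = 0.2, delta = 4,
                                   seed_frac = 0.05, sd = 0.03) {
  n_c <- round(n * prop_cannibal)
  is_c <- c(rep(TRUE, n_c), rep(FALSE, n - n_c))
  base <- c(HW = 1.0, JW1 = 0.8, JW2 = 0.7, EW = 0.5, HL1 = 0.6, HL2 = 0.9, HL3 = 1.2, SVL = 6.0)
  bump <- c(HW = 1, JW1 = 1.6, JW2 = 1.4, EW = 0.3, HL1 = 0.8, HL2 = 0.8, HL3 = 0.6, SVL = 1.2)
  m <- sapply(names(base), function(d) {
    base[[d]] + is_c * delta * sd * bump[[d]] + rnorm(n, 0, sd)
  })
  m <- abs(m) + 0.01
  df <- tibble::as_tibble(m)
  df$SVL <- df$SVL + 5 # keep SVL > HW robustly
  df$specimen_id <- sprintf("s%03d", seq_len(n))
  seeded <- is_c & (runif(n) < seed_frac / prop_cannibal)
  if (any(is_c) && !any(seeded)) seeded[which(is_c)[1]] <- TRUE
  df$stomach_conspecific <- seeded
  df$visual_cannibal <- FALSE
  list(measurements = df, truth = is_c)
}

# Per-specimen meta table for a synthetic study, using ground-truth labels.
study_meta <- function(study) {
  tr <- study$truth
  tibble::tibble(
    specimen_id = study$measurements$specimen_id,
    SVL = study$measurements$SVL,
    category = tr$category[match(study$measurements$specimen_id, tr$specimen_id)],
    population = study$measurements$tank_id
  )
}

# Compact generator settings for repeated-simulation tests: fewer, smaller
# tanks so a full scoring pass stays fast.
compact_params <- function(...) {
  generator_params(n_tanks = 5, n_per_tank = 14, n_solitary = 10, victim_range = 1:6, ...)
}
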