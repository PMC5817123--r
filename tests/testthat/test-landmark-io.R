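test_that("TPS records parse with scale calibration, ids and record order", {
  tf <- withr::local_tempfile(fileext = ".tps")
  writeLines(c(
    "LM=3", "0 0", "1 0", "0 1", "ID=s1", "SCALE=2.0",
    "LM=3", "1 1", "2 1", "1 2", "ID=s2"
  ), tf)
  lm <- read_tps(tf)
  expect_equal(unique(lm$specimen_id), c("s1", "s2")) # order preserved
  s1 <- lm[lm$specimen_id == "s1", ]
  expect_equal(cbind(s1$x, s1$y), rbind(c(0, 0), c(2, 0), c(0, 2))) # scaled
  s2 <- lm[lm$specimen_id == "s2", ]
  expect_equal(s2$x, c(1, 2, 1)) # no SCALE key: raw coordinates
  meta <- attr(lm, "tps_meta")
  expect_equal(meta$scale, c(2, NA))
})

test_that("LM3= dialect headers are accepted", {
  tf <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM3=3", "0 0", "1 0", "0 1", "ID=a"), tf)
  expect_equal(nrow(read_tps(tf)), 3)
})

test_that("write/read round-trip preserves coordinates and ids exactly", {
  set.seed(41)
  lm <- dplyr::bind_rows(lapply(1:4, function(i) {
    tibble::tibble(
      specimen_id = sprintf("sp%d", i), point = 1:7,
      x = rnorm(7, sd = 10), y = rnorm(7, sd = 10)
    )
  }))
  tf <- withr::local_tempfile(fileext = ".tps")
  write_tps(lm, tf)
  back <- read_tps(tf)
  expect_equal(back$specimen_id, lm$specimen_id)
  expect_equal(back$x, lm$x, tolerance = 1e-9)
  expect_equal(back$y, lm$y, tolerance = 1e-9)
})

test_that("malformed TPS input raises parse errors naming the problem", {
  tf <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=4", "0 0", "1 0", "0 1", "ID=s1"), tf)
  expect_error(read_tps(tf), "LM=4 declared but only 3")
  writeLines(c("LM=2", "0 0", "1 zebra"), tf)
  expect_error(read_tps(tf), "line 3")
  expect_error(read_tps(file.path(tempdir(), "nope.tps")), "not found")
})

test_that("semilandmarks are equally spaced by arc length", {
  # straight segment
  r <- resample_semilandmarks(rbind(c(0, 0), c(0, 3)), 2)
  expect_equal(cbind(r$x, r$y), rbind(c(0, 1), c(0, 2)))
  # right-angle polyline, total length 2: midpoint is the corner
  r <- resample_semilandmarks(rbind(c(0, 0), c(1, 0), c(1, 1)), 1)
  expect_equal(cbind(r$x, r$y), rbind(c(1, 0)))
  # degenerate curve
  expect_error(resample_semilandmarks(rbind(c(1, 1), c(1, 1)), 1), "zero-length")
})

test_that("densely sampled circle arc resamples onto equal-angle points", {
  theta <- seq(0, pi / 2, length.out = 20001)
  arc <- cbind(cos(theta), sin(theta))
  r <- resample_semilandmarks(arc, 3)
  expected_angles <- pi / 2 * (1:3) / 4
  expect_equal(r$x, cos(expected_angles), tolerance = 1e-3)
  expect_equal(r$y, sin(expected_angles), tolerance = 1e-3)
})

test_that("resampling is stable under refinement of the input polyline", {
  set.seed(11)
  pts <- cbind(cumsum(runif(6)), cumsum(rnorm(6)))
  dense <- do.call(rbind, lapply(seq_len(nrow(pts) - 1), function(i) {
    f <- seq(0, 1, length.out = 50)
    cbind(
      pts[i, 1] + f * (pts[i + 1, 1] - pts[i, 1]),
      pts[i, 2] + f * (pts[i + 1, 2] - pts[i, 2])
    )
  }))
  a <- resample_semilandmarks(pts, 4)
  b <- resample_semilandmarks(dense, 4)
  expect_equal(as.matrix(a), as.matrix(b), tolerance = 1e-6)
})

test_that("census tables validate the victim-count identity on load", {
  tf <- withr::local_tempfile(fileext = ".csv")
  ok <- tibble::tibble(
    tank_id = c("g1", "g2"), n_initial = c(30, 30),
    n_survivors = c(27, 25), n_cannibals = c(2, 3)
  )
  write_census_csv(ok, tf)
  back <- read_census_csv(tf)
  expect_equal(back$n_victims, c(3L, 5L))
  expect_equal(back[names(ok)], ok, ignore_attr = TRUE)
  # inconsistent victim column rejected
  bad <- ok
  bad$n_victims <- c(1, 1)
  expect_error(validate_census(bad), "n_initial - n_survivors")
  # cannibals exceeding survivors rejected
  bad2 <- ok
  bad2$n_cannibals <- c(28, 3)
  expect_error(validate_census(bad2), "exceed")
  expect_error(
    read_census_csv({
      writeLines("tank_id,n_initial\ng1,30", tf)
      tf
    }),
    "missing required column"
  )
})

test_that("measurement tables validate lengths and flags and round-trip", {
  tf <- withr::local_tempfile(fileext = ".csv")
  m <- tibble::tibble(
    specimen_id = c("a", "b"),
    HW = c(1, 1.1), JW1 = c(0.9, 1.0), JW2 = c(0.8, 0.9), EW = c(0.5, 0.6),
    HL1 = c(0.6, 0.7), HL2 = c(0.9, 1.0), HL3 = c(1.2, 1.3), SVL = c(6, 7),
    stomach_conspecific = c(FALSE, TRUE), visual_cannibal = c(FALSE, FALSE)
  )
  write_measurements_csv(m, tf)
  expect_equal(read_measurements_csv(tf), m, ignore_attr = TRUE)
  bad <- m
  bad$SVL[1] <- 0.5 # SVL must exceed HW
  expect_error(validate_measurements(bad), "SVL")
  expect_error(validate_measurements(m[, -2]), "missing required column")
})

test_that("landmark schemas validate their pair and midline maps", {
  s <- default_dorsal_schema()
  expect_s3_class(s, "landmark_schema")
  expect_length(s$roles, 39)
  expect_equal(nrow(s$pairs), 19)
  expect_equal(s$midline, 1L)
  expect_length(default_lateral_schema()$roles, 20)
  expect_error(
    landmark_schema(rep("fixed", 4), pairs = rbind(c(1, 5))),
    "out of range"
  )
  expect_error(
    landmark_schema(rep("fixed", 4), pairs = rbind(c(1, 2)), midline = 2L),
    "disjoint"
  )
})
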