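# Micromotion metric against independent geometric oracles.

test_that("bone and implant moving rigidly together give zero micromotion", {
  Rmot <- function(t) rotz(0.02 * (t - 1))
  cmot <- function(t) c(0.1, -0.05, 0.2) * (t - 1)
  h <- make_synthetic_history(
    motion = function(t, x) sweep(x %*% t(Rmot(t)), 2, cmot(t), `+`),
    bone_motion = function(t, x) sweep(x %*% t(Rmot(t)), 2, cmot(t), `+`))
  fl <- micromotion_field(project_and_track(h, 1), gap_threshold = 10)
  expect_lt(max(fl$value_um, na.rm = TRUE), 1e-9)
})

test_that("a pure tangential shift is recovered exactly", {
  d <- 0.042     # mm
  h <- make_synthetic_history(
    motion = function(t, x) {
      x[, 1] <- x[, 1] + d * (t > 1); x
    })
  fl <- micromotion_field(project_and_track(h, 1), gap_threshold = 10)
  expect_lt(max(abs(fl$value_um - d * 1000), na.rm = TRUE), 1e-9)
})

test_that("constant and sinusoidal traces give their known maxima", {
  h_const <- make_synthetic_history(
    motion = function(t, x) { x[, 2] <- x[, 2] + 0.030 * (t > 1); x })
  fl <- micromotion_field(project_and_track(h_const, 1), gap_threshold = 10)
  expect_equal(unname(fl$value_um[fl$included]),
               rep(30, length(fl$included)), tolerance = 1e-9)

  h_sin <- make_synthetic_history(
    n_inc = 11,
    motion = function(t, x) {
      x[, 1] <- x[, 1] + 0.050 * sin(pi * (t - 1) / 10); x
    })
  fl2 <- micromotion_field(project_and_track(h_sin, 1), gap_threshold = 10)
  expect_equal(unname(fl2$value_um[fl2$included]),
               rep(50, length(fl2$included)), tolerance = 1e-9)
})

test_that("random scripted histories match the brute-force oracle", {
  for (seed in 1:3) {
    set.seed(100 + seed)
    drift <- matrix(rnorm(30, sd = 0.02), 10, 3)
    h <- make_synthetic_history(
      n_nodes = 10, n_inc = 8, seed = seed,
      motion = function(t, x) x + drift * (t - 1) +
        0.005 * sin(t) * matrix(rep(c(1, -1, 0.3), each = nrow(x)), ncol = 3))
    got <- micromotion_field(project_and_track(h, 1), gap_threshold = 10)
    want <- oracle_micromotion(h, 1)
    expect_equal(unname(got$value_um), want, tolerance = 1e-12)
  }
})

test_that("the metric is invariant under a common rigid transform of the history", {
  set.seed(17)
  drift <- matrix(rnorm(36, sd = 0.02), 12, 3)
  mk <- function(R, c0) make_synthetic_history(
    n_nodes = 12, n_inc = 6, seed = 5,
    motion = function(t, x) sweep((x + drift * (t - 1)) %*% t(R), 2, c0, `+`),
    bone_motion = function(t, x) sweep(x %*% t(R), 2, c0, `+`))
  h1 <- mk(diag(3), c(0, 0, 0))
  h2 <- mk(rotz(0.7), c(10, -5, 3))
  v1 <- micromotion_field(project_and_track(h1, 1), 10)$value_um
  v2 <- micromotion_field(project_and_track(h2, 1), 10)$value_um
  expect_equal(v1, v2, tolerance = 1e-9)
})

test_that("large-gap nodes are excluded and exclusion never raises the peak", {
  set.seed(23)
  h <- make_synthetic_history(n_nodes = 14, n_inc = 6, gap0 = 0.05,
    motion = function(t, x) {
      x[, 1] <- x[, 1] + 0.01 * (t - 1) * seq_len(nrow(x)) / nrow(x)
      x[1:4, 3] <- x[1:4, 3] + 2          # large normal gap region
      x
    })
  tr <- project_and_track(h, 1)
  f_loose <- micromotion_field(tr, gap_threshold = 10)
  f_tight <- micromotion_field(tr, gap_threshold = 0.5)
  expect_identical(unname(f_tight$exclusion_reason[1]), "large normal gap")
  expect_gt(length(f_tight$excluded), length(f_loose$excluded))
  expect_lte(max(f_tight$value_um, na.rm = TRUE),
             max(f_loose$value_um, na.rm = TRUE))
  expect_error(micromotion_field(tr, gap_threshold = -1), "empty inclusion")
})

test_that("summaries use the linear-interpolation percentile and area weights", {
  field <- structure(list(
    value_um = 1:100, included = 1:100, excluded = integer(0),
    exclusion_reason = rep(NA_character_, 100), area = rep(1, 100),
    time_of_peak = rep(1L, 100), gap_threshold = 0.5
  ), class = "micromotion_field")
  s <- summarize_micromotion(field, threshold = 112)
  expect_equal(s$peak, 100)
  expect_equal(s$p95, 95.05)
  expect_equal(s$area_fraction_below_threshold, 1.0)
  expect_lte(s$p95, s$peak)

  field$value_um <- rep(40, 100)
  s2 <- summarize_micromotion(field)
  expect_equal(s2$peak, 40)
  expect_equal(s2$p95, 40)

  # area weighting of the threshold map
  field$value_um <- c(rep(200, 10), rep(10, 90))
  field$area <- c(rep(2, 10), rep(1, 90))
  s3 <- summarize_micromotion(field, threshold = 112)
  expect_equal(s3$area_fraction_below_threshold, 90 / 110)
})
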