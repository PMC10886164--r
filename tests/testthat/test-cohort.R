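test_that("cohort sampling respects configured ranges and identities", {
  co <- sample_cohort(n_patients = 41, seed = 7)
  expect_true(all(co$age >= 46 & co$age <= 75))
  expect_true(all(co$bmi >= 18 & co$bmi <= 49))
  expect_true(all(co$height >= 1.55 & co$height <= 1.99))
  expect_true(all(co$weight >= 52 & co$weight <= 170))
  expect_true(all(abs(co$bmi - co$weight / co$height^2) < 1e-9 * co$bmi))
  expect_true(all(co$side %in% c("left", "right")))
  # demographics identical across a patient's tibiae
  for (p in unique(co$patient_id)) {
    rows <- co[co$patient_id == p, ]
    expect_true(all(rows$age == rows$age[1]))
    expect_true(all(rows$weight == rows$weight[1]))
  }
})

test_that("cohort sampling is bit-reproducible under a fixed seed", {
  a <- sample_cohort(n_patients = 41, seed = 123)
  b <- sample_cohort(n_patients = 41, seed = 123)
  expect_identical(a, b)
  d <- sample_cohort(n_patients = 41, seed = 124)
  expect_false(identical(a, d))
})

test_that("sampled BMI matches the configured joint distribution", {
  # independent oracle: brute-force resampling of the same configured
  # model (truncated normals + joint weight-range rejection) with plain R
  cfg <- demographics_default()
  set.seed(99)
  N <- 2e5
  h <- numeric(0); b <- numeric(0)
  while (length(b) < N) {
    hh <- rnorm(N, cfg$height$mean, cfg$height$sd)
    bb <- rnorm(N, cfg$bmi$mean, cfg$bmi$sd)
    ok <- hh >= cfg$height$min & hh <= cfg$height$max &
      bb >= cfg$bmi$min & bb <= cfg$bmi$max
    w <- bb * hh^2
    ok <- ok & w >= cfg$weight_range[1] & w <= cfg$weight_range[2]
    h <- c(h, hh[ok]); b <- c(b, bb[ok])
  }
  mu_ref <- mean(b[1:N]); sd_ref <- sd(b[1:N])

  co <- sample_cohort(n_patients = 10000, seed = 5)
  pat <- co[!duplicated(co$patient_id), ]
  se <- sd_ref / sqrt(nrow(pat))
  expect_lt(abs(mean(pat$bmi) - mu_ref), 3 * se)
})

test_that("invalid demographic ranges are rejected", {
  cfg <- demographics_default()
  cfg$age$min <- 80; cfg$age$max <- 40
  expect_error(sample_cohort(cfg, 5, 1), "min > max")
  expect_error(sample_cohort(n_patients = 0, seed = 1), ">= 1")
})

test_that("cohort CSV round-trips", {
  co <- sample_cohort(n_patients = 5, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  co2 <- read_cohort_csv(f)
  expect_equal(as.data.frame(co), as.data.frame(co2), tolerance = 1e-12)
})
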