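test_that("the factorial plan covers tibiae x materials x activities", {
  co1 <- tiny_cohort(1, seed = 21)[1, , drop = FALSE]
  p1 <- build_plan(co1, seed = 1)
  expect_identical(nrow(p1), 4L)

  co <- tiny_cohort(10, seed = 3)
  p <- build_plan(co, seed = 1)
  expect_identical(nrow(p), nrow(co) * 4L)
  # exhaustive duplicate scan
  key <- paste(p$model_id, p$tray_material, p$activity)
  expect_identical(anyDuplicated(key), 0L)
  expect_true(all(p$seed < 2^31))
})

test_that("REML recovers a known BMI slope and covers it", {
  set.seed(31)
  co <- sample_cohort(n_patients = 200, seed = 31)
  b <- rnorm(200, sd = 3)
  names(b) <- unique(co$patient_id)
  y <- 10 + 1.5 * co$bmi + b[co$patient_id] + rnorm(nrow(co), sd = 4)
  d <- cbind(co, p95_um = y)
  fit <- fit_lmm(d)
  bmi <- fit$fixed[fit$fixed$effect == "bmi", ]
  expect_gt(bmi$estimate, 1.0)
  expect_lt(bmi$estimate, 2.0)
  expect_true(bmi$ci_low <= 1.5 && 1.5 <= bmi$ci_high)
  expect_gt(fit$ranef_var, 0)
})

test_that("the LMM reduces to OLS when the patient variance vanishes", {
  # a fixture whose REML variance estimate sits at the boundary (zero)
  set.seed(53)
  co <- sample_cohort(n_patients = 120, seed = 53)
  # no patient effect at all: the REML variance estimate sits at the
  # boundary and fixed effects coincide with least squares
  y <- 5 + 0.8 * co$bmi + 0.1 * co$age + rnorm(nrow(co), sd = 2)
  d <- cbind(co, p95_um = y)
  fit <- suppressMessages(fit_lmm(d))
  ols <- stats::lm(p95_um ~ gender + age + bmi,
                   data = transform(d, gender = factor(gender, c("F", "M"))))
  expect_equal(fit$ranef_var, 0, tolerance = 1e-8)
  expect_equal(fit$fixed$estimate, unname(coef(ols)), tolerance = 1e-6)
})

test_that("balanced genders with identical outcomes give a null gender effect", {
  set.seed(51)
  n <- 200
  co <- data.frame(
    patient_id = rep(sprintf("P%03d", 1:n), each = 2),
    side = rep(c("left", "right"), n),
    gender = rep(rep(c("F", "M"), each = n / 2), each = 2),
    age = rep(runif(n, 50, 70), each = 2),
    height = 1.7, weight = 75, bmi = rep(runif(n, 20, 35), each = 2))
  co$p95_um <- 30 + rnorm(2 * n, sd = 5)  # same distribution in both groups
  fit <- suppressMessages(fit_lmm(co))
  g <- fit$fixed[fit$fixed$effect == "genderM", ]
  expect_lt(abs(g$estimate), 2 * g$se)
})

test_that("constant covariates are rejected with the column named", {
  co <- tiny_cohort(4, seed = 61)
  co$gender <- "F"
  co$p95_um <- rnorm(nrow(co))
  expect_error(fit_lmm(co), "gender")
})

test_that("cohort report matches sort-based medians and flags degeneracy", {
  set.seed(71)
  rows <- expand.grid(model_id = sprintf("T%02d", 1:6),
                      material = c("PEEK", "titanium"),
                      activity = c("gait", "squat"),
                      stringsAsFactors = FALSE)
  rows$patient_id <- substr(rows$model_id, 1, 3)
  rows$p95_um <- runif(nrow(rows), 5, 60)
  rep <- cohort_report(rows)
  for (nm in names(rep$distributions)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    x <- rows$p95_um[rows$material == parts[1] & rows$activity == parts[2]]
    xs <- sort(x); n <- length(xs)
    med <- if (n %% 2 == 1) xs[(n + 1) / 2] else mean(xs[n / 2 + 0:1])
    expect_equal(rep$distributions[[nm]]$median, med)
  }
  # one difference row per (tibia, activity)
  expect_identical(nrow(rep$differences), 6L * 2L)
  expect_identical(rep$threshold, 112)

  rows$p95_um <- 25
  rep2 <- cohort_report(rows)
  expect_true(all(vapply(rep2$distributions,
                         function(s) s$density$degenerate, TRUE)))
  expect_true(all(vapply(rep2$distributions, function(s) s$iqr, 0) == 0))
})

test_that("run_plan is deterministic and resumable", {
  co <- tiny_cohort(1, seed = 3)[1, , drop = FALSE]
  cfg <- desk_config()
  plan <- build_plan(co, seed = 5, materials = "PEEK", activities = "gait")
  cache <- file.path(tempdir(), "tf_cache")
  unlink(cache, recursive = TRUE)
  r1 <- run_plan(plan, co, cfg, cache_dir = cache)
  r2 <- run_plan(plan, co, cfg, cache_dir = cache)    # from cache
  expect_equal(as.data.frame(r1), as.data.frame(r2), tolerance = 1e-8)
  r3 <- run_plan(plan, co, cfg)                       # fresh recompute
  expect_equal(r1$p95_um, r3$p95_um, tolerance = 1e-12)
  expect_length(attr(r1, "failures"), 0)
})
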