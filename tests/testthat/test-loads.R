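test_that("activity profiles have the prescribed increment counts and peak", {
  g <- build_load_profile("gait", bodyweight = 75)
  expect_identical(g$n_increments, 73L)
  expect_equal(max(g$medial_force + g$lateral_force), 1514, tolerance = 1e-9)
  s <- build_load_profile("squat", bodyweight = 75)
  expect_identical(s$n_increments, 67L)
  expect_equal(max(s$medial_force + s$lateral_force), 1514, tolerance = 1e-9)
  expect_error(build_load_profile("jump", 75))
  expect_error(build_load_profile("gait", -3))
})

test_that("forces are non-negative and scale exactly linearly in bodyweight", {
  for (act in c("gait", "squat")) {
    p1 <- build_load_profile(act, bodyweight = 80)
    p2 <- build_load_profile(act, bodyweight = 160)
    expect_true(all(p1$medial_force >= 0))
    expect_true(all(p1$lateral_force >= 0))
    expect_equal(p2$medial_force, 2 * p1$medial_force, tolerance = 1e-12)
    expect_equal(p2$lateral_force, 2 * p1$lateral_force, tolerance = 1e-12)
    expect_equal(max(p2$medial_force + p2$lateral_force),
                 2 * max(p1$medial_force + p1$lateral_force),
                 tolerance = 1e-12)
  }
})

test_that("centres of pressure stay inside their articular compartments", {
  for (act in c("gait", "squat")) {
    p <- build_load_profile(act, bodyweight = 90,
                            insert_halfwidth = 20, insert_halfdepth = 13)
    expect_true(all(p$cop_medial[, 1] < 0))          # medial half
    expect_true(all(p$cop_lateral[, 1] > 0))         # lateral half
    expect_true(all(abs(p$cop_medial[, 1]) <= 20))
    expect_true(all(abs(p$cop_medial[, 2]) <= 13))
    expect_true(all(abs(p$cop_lateral[, 1]) <= 20))
    expect_true(all(abs(p$cop_lateral[, 2]) <= 13))
  }
})
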