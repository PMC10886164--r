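test_that("generated tibia surfaces are watertight genus-0 meshes", {
  co <- tiny_cohort()
  tib <- generate_tibia(co[1, ], seed = 3)
  wt <- is_watertight(tib$surface)
  expect_true(as.logical(wt))
  expect_identical(attr(wt, "euler"), 2L)
  expect_gt(tibiofit:::mesh_volume(tib$surface), 0)
})

test_that("left and right tibiae are mirror images before noise", {
  spec <- tibia_spec(noise_amp = 0)
  pl <- list(height = 1.71, side = "left")
  pr <- list(height = 1.71, side = "right")
  tl <- generate_tibia(pl, spec, seed = 5, apply_pose_noise = FALSE)
  tr <- generate_tibia(pr, spec, seed = 5, apply_pose_noise = FALSE)
  vl <- tl$surface$vertices
  vr <- tr$surface$vertices
  vr_m <- vr; vr_m[, 1] <- -vr_m[, 1]
  expect_lt(max(abs(vl - vr_m)), 1e-9)
})

test_that("HU field shows cortical shell over trabecular interior", {
  co <- tiny_cohort()
  spec <- tibia_spec(cortical_hu = 1200, trabecular_hu = 300)
  tib <- generate_tibia(co[1, ], spec, seed = 9, apply_pose_noise = FALSE)
  # shaft level: shell points just inside the surface vs core points
  theta <- seq(0, 2 * pi, length.out = 40)[-40]
  z <- -80
  rs <- tibiofit:::tibia_radius(theta, z, spec, tib$scale, tib$shape_noise)
  shell <- cbind((rs - 1.0) * cos(theta), (rs - 1.0) * sin(theta), z)
  core <- cbind(0.2 * rs * cos(theta), 0.2 * rs * sin(theta), z)
  expect_gt(mean(sample_hu(tib, shell)), mean(sample_hu(tib, core)))
  expect_gt(mean(sample_hu(tib, shell)), 700)
  expect_lt(mean(sample_hu(tib, core)), 600)
})

test_that("landmarks sit within the mesh extent and carry the pose", {
  co <- tiny_cohort()
  tib <- generate_tibia(co[1, ], seed = 13)
  bb <- apply(tib$surface$vertices, 2, range)
  lm <- tib$landmarks
  for (i in seq_len(nrow(lm))) {
    expect_true(all(lm[i, ] >= bb[1, ] - 1e-6 & lm[i, ] <= bb[2, ] + 1e-6))
  }
})
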