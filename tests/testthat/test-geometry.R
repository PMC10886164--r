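cut_fixture <- local({
  env <- new.env()
  function() {
    if (is.null(env$cs)) {
      co <- tiny_cohort()
      env$tib <- generate_tibia(co[1, ], seed = 3, apply_pose_noise = FALSE)
      env$fr <- assign_frame(env$tib)
      env$cs <- cut_bone(env$tib, env$fr, geometry_config(edge_scale = 4))
    }
    env
  }
})

test_that("bone cuts sit at the configured levels", {
  fx <- cut_fixture()
  expect_equal(abs(fx$cs$z_prox), 8.9, tolerance = 1e-9)
  expect_equal(abs(fx$cs$z_dist), 100, tolerance = 1e-9)
  # distance from the joint line (z = 0) to the distal face is exactly the
  # configured distal cut level
  expect_equal(fx$cs$z_prox - fx$cs$z_dist, 100 - 8.9, tolerance = 1e-9)

  cs0 <- cut_bone(fx$tib, fx$fr, geometry_config(proximal_cut_depth = 1e-9))
  expect_lt(abs(cs0$z_prox), 1e-6)   # degenerate depth: at the joint line
})

test_that("cut planes miss-mesh errors are raised", {
  fx <- cut_fixture()
  expect_error(cut_bone(fx$tib, fx$fr, geometry_config(distal_cut_level = 500)),
               "misses")
})

test_that("tray sizing maximises coverage under the overhang bound", {
  fx <- cut_fixture()
  cat <- implant_catalog()
  sel <- select_tray_size(fx$cs$outline, cat, max_overhang = 2)
  tab <- sel$candidates
  # exhaustive check: the returned size is the feasible size with maximal
  # coverage (ties toward the smaller index)
  feas <- tab[tab$overhang <= 2, ]
  best <- feas$size[order(-feas$coverage, feas$size)][1]
  expect_identical(sel$size, best)
  expect_lte(sel$overhang, 2)

  # independent overhang verification at the chosen placement: dense
  # boundary samples against the outline polygon
  entry <- cat$sizes[[sel$size]]
  fp <- tibiofit:::resample_closed(entry$outline, 720)
  fp[, 1] <- fp[, 1] + sel$placement$translation[1]
  fp[, 2] <- fp[, 2] + sel$placement$translation[2]
  d <- tibiofit:::points_polygon_signed(fp, fx$cs$outline)
  expect_lte(max(d), 2 + 0.05)   # dense resampling may add a hair
})

test_that("a footprint identical to the outline fits exactly", {
  cat <- implant_catalog()
  entry <- cat$sizes[[3]]
  sel <- select_tray_size(entry$outline, cat, max_overhang = 2)
  expect_equal(sel$size, 3)
  expect_lte(sel$overhang, 1e-3)
})

test_that("shrinking the outline never selects a larger size", {
  fx <- cut_fixture()
  cat <- implant_catalog()
  sel_full <- select_tray_size(fx$cs$outline, cat, 2)
  shrunk <- fx$cs$outline
  ctr <- colMeans(shrunk)
  shrunk <- sweep(shrunk, 2, ctr) * 0.9
  shrunk <- sweep(shrunk, 2, ctr, `+`)
  sel_small <- select_tray_size(shrunk, cat, 2)
  expect_lte(sel_small$size, sel_full$size)
})

test_that("an impossible outline produces a sizing error naming the overhang", {
  cat <- implant_catalog()
  tiny <- cbind(10 * cos(seq(0, 2 * pi, length.out = 60)[-60]),
                10 * sin(seq(0, 2 * pi, length.out = 60)[-60]))
  expect_error(select_tray_size(tiny, cat, 2), "overhang")
})
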