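test_that("anatomical frame matches global axes for a canonical tibia", {
  tib <- generate_tibia(list(height = 1.71, side = "right"),
                        tibia_spec(noise_amp = 0), seed = 1,
                        apply_pose_noise = FALSE)
  fr <- assign_frame(tib)
  expect_lt(max(abs(fr$axes["pd", ] - c(0, 0, 1))), 1e-6)
  expect_lt(max(abs(abs(fr$axes["ml", ]) - c(1, 0, 0))), 1e-6)
  expect_equal(det(fr$axes), 1, tolerance = 1e-9)
})

test_that("the frame co-rotates with the mesh", {
  tib <- generate_tibia(list(height = 1.71, side = "right"),
                        tibia_spec(noise_amp = 0), seed = 1,
                        apply_pose_noise = FALSE)
  fr0 <- assign_frame(tib)
  R <- tibiofit:::rot_xyz(c(0.3, -0.2, 0.5))
  tib2 <- tib
  tib2$surface$vertices <- tib$surface$vertices %*% t(R)
  tib2$landmarks <- tib$landmarks %*% t(R)
  fr1 <- assign_frame(tib2)
  for (ax in c("pd", "ml", "ap")) {
    expect_lt(max(abs(fr1$axes[ax, ] - as.numeric(R %*% fr0$axes[ax, ]))), 1e-6)
  }
})

test_that("mirroring flips the medial-lateral axis but keeps right-handedness", {
  spec <- tibia_spec(noise_amp = 0)
  tl <- generate_tibia(list(height = 1.71, side = "left"), spec, seed = 2,
                       apply_pose_noise = FALSE)
  tr <- generate_tibia(list(height = 1.71, side = "right"), spec, seed = 2,
                       apply_pose_noise = FALSE)
  fl <- assign_frame(tl); fr <- assign_frame(tr)
  expect_lt(max(abs(fl$axes["ml", ] + fr$axes["ml", ])), 1e-6)
  expect_equal(det(fl$axes), 1, tolerance = 1e-9)
  expect_equal(det(fr$axes), 1, tolerance = 1e-9)
})

test_that("degenerate collinear landmarks are rejected", {
  lmk <- rbind(medial_condyle = c(-1, 0, 0),
               lateral_condyle = c(1, 0, 0),
               shaft_distal = c(3, 0, 0))
  expect_error(assign_frame(list(landmarks = lmk)), "collinear")
})

test_that("rigid CPD recovers identity and known transforms", {
  set.seed(4)
  Y <- matrix(rnorm(240), ncol = 3) * 10
  tf0 <- cpd_rigid(Y, Y)
  expect_lt(max(abs(tf0$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(tf0$translation)), 1e-6)

  R <- rotz(15 * pi / 180)
  t0 <- c(5, 3, 1)
  X <- sweep(Y %*% t(R), 2, t0, `+`)
  tf <- cpd_rigid(Y, X)
  ang_err <- acos(pmin(1, (sum(diag(t(tf$rotation) %*% R)) - 1) / 2))
  expect_lt(ang_err, 1e-3)
  expect_lt(max(abs(tf$translation - t0)), 1e-3)
})

test_that("rigid CPD tolerates jitter and is invariant to ordering", {
  set.seed(11)
  Y <- matrix(rnorm(300), ncol = 3) * 10
  R <- rotz(12 * pi / 180); t0 <- c(2, -4, 6)
  X <- sweep(Y %*% t(R), 2, t0, `+`)
  Xj <- X + matrix(rnorm(length(X), sd = 0.1), ncol = 3)   # ~1% jitter
  tf <- cpd_rigid(Y, Xj)
  ang_err <- acos(pmin(1, (sum(diag(t(tf$rotation) %*% R)) - 1) / 2))
  expect_lt(ang_err, pi / 180)                      # within 1 degree

  perm <- sample(nrow(Y))
  tf_p <- cpd_rigid(Y[perm, ], Xj)
  expect_lt(max(abs(tf_p$rotation - tf$rotation)), 1e-6)

  # common rigid motion of both clouds leaves the relative transform
  # unchanged (conjugation identity)
  Q <- rotz(-0.4); c0 <- c(1, 2, 3)
  Y2 <- sweep(Y %*% t(Q), 2, c0, `+`)
  X2 <- sweep(Xj %*% t(Q), 2, c0, `+`)
  tf2 <- cpd_rigid(Y2, X2)
  R_expected <- Q %*% tf$rotation %*% t(Q)
  expect_lt(max(abs(tf2$rotation - R_expected)), 1e-4)
})

test_that("transform utilities compose and invert correctly", {
  a <- rigid_transform(rotz(0.3), c(1, 2, 3))
  b <- rigid_transform(rotz(-0.7), c(-2, 0, 5))
  p <- matrix(rnorm(30), ncol = 3)
  expect_equal(apply_transform(compose_transform(a, b), p),
               apply_transform(a, apply_transform(b, p)), tolerance = 1e-12)
  ident <- compose_transform(a, invert_transform(a))
  expect_lt(max(abs(ident$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(ident$translation)), 1e-12)
})
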