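# Contact law and press-fit solver behaviour on small fixtures.

test_that("an open interface with zero fit transmits no force", {
  cm <- tibiofit:::coulomb_fixture()
  st <- tibiofit:::new_solver_state(cm)
  # lift the implant block: positive gap everywhere, fit zero
  u <- numeric(cm$model$ndof)
  top_block <- (cm$n_bone_nodes + 1):nrow(cm$model$mesh$nodes)
  u[tibiofit:::node_dofs(top_block, 3)] <- 0.5
  cu <- contact_update(cm$pairs, u, cm$model$mesh$nodes, st, cm$params, 0)
  expect_true(all(cu$status == "open"))
  expect_equal(max(abs(cu$f)), 0)
  expect_true(all(cu$pressure == 0))
})

test_that("Coulomb stick below the limit and steady sliding at the limit", {
  b <- benchmark_coulomb(N = 1000, mu = 0.5, stick_fraction = 0.49)
  expect_true(all(names(b$stick$status) == "stick"))
  expect_equal(b$stick$tangential_reaction, b$stick$applied,
               tolerance = 1e-6)
  expect_equal(b$stick$max_anchor_slip, 0)
  expect_lt(abs(b$slide$ratio - 1), 0.01)
  expect_true(all(names(b$slide$status) == "slip"))
})

test_that("zero interference implantation leaves the model undeformed", {
  cm <- tibiofit:::coulomb_fixture()
  cm$params$interference_fit <- 0
  st <- virtual_implantation(cm, solver_control())
  expect_lt(max(abs(st$u)), 1e-10)
  expect_true(all(st$pressure == 0))
})

test_that("the ramped offset is realized at the interface within penalty compliance", {
  l <- benchmark_interference()
  expect_equal(l$realized_offset_mm, l$fit_mm,
               tolerance = 2 * l$penalty_compliance_mm / l$fit_mm)
  expect_gt(l$realized_offset_mm / l$fit_mm, 0.9)
})

test_that("press-fit interface pressure matches the Lame closed form", {
  l <- benchmark_interference()
  expect_lt(l$rel_error, 0.15)
})

test_that("distal reactions balance the applied load at equilibrium", {
  cm <- tibiofit:::coulomb_fixture()
  ctrl <- solver_control(tol_rel = 1e-9, max_iter = 40)
  st <- tibiofit:::new_solver_state(cm)
  cache <- new.env(parent = emptyenv())
  cache$free <- setdiff(seq_len(cm$model$ndof), cm$fixed_dofs)
  cache$chol <- NULL; cache$last_status <- NULL
  fN <- numeric(cm$model$ndof)
  fN[tibiofit:::node_dofs(cm$load_nodes, 3)] <- -1500 / length(cm$load_nodes)
  st$external_force <- numeric(cm$model$ndof)
  for (k in 1:2) st <- tibiofit:::solve_step(cm, st, fN, 0, ctrl, cache)
  fT <- fN
  fT[tibiofit:::node_dofs(cm$load_nodes, 1)] <- 200 / length(cm$load_nodes)
  st <- tibiofit:::solve_step(cm, st, fT, 0, ctrl, cache)
  rb <- reaction_balance(cm, st)
  expect_lt(rb$residual_rel, 1e-6)
  expect_equal(rb$applied[3], -1500, tolerance = 1e-9)
})

test_that("tangential tractions never exceed the Coulomb bound", {
  fx <- fixture_implanted("PEEK")
  st <- fx$st
  cu <- contact_update(fx$cm$pairs, st$u, fx$cm$model$mesh$nodes, st,
                       fx$cm$params, st$fit)
  tmag <- sqrt(cu$traction[, 1]^2 + cu$traction[, 2]^2)
  mu <- fx$cm$params$friction_coefficient
  bound <- mu * pmax(cu$normal_force,
                     st$pressure * fx$cm$pairs$tributary_area)
  expect_true(all(tmag <= bound * (1 + 1e-6) + 1e-9))
})

test_that("doubling the load doubles displacements in the linear sub-regime", {
  cm <- tibiofit:::coulomb_fixture(mu = 0)      # frictionless, elastic
  ctrl <- solver_control()
  press <- function(N) {
    st <- tibiofit:::new_solver_state(cm)
    cache <- new.env(parent = emptyenv())
    cache$free <- setdiff(seq_len(cm$model$ndof), cm$fixed_dofs)
    cache$chol <- NULL; cache$last_status <- NULL
    f <- numeric(cm$model$ndof)
    f[tibiofit:::node_dofs(cm$load_nodes, 3)] <- -N / length(cm$load_nodes)
    st$external_force <- numeric(cm$model$ndof)
    tibiofit:::solve_step(cm, st, f, 0, ctrl, cache)
  }
  s1 <- press(500); s2 <- press(1000)
  expect_lt(max(abs(s2$u - 2 * s1$u)), 1e-6 * max(abs(s1$u)))
})

test_that("a zero-force profile leaves the interface kinematics constant", {
  fx <- fixture_implanted("PEEK")
  lp <- build_load_profile("gait", bodyweight = 75, n_cycles = 1)
  lp$medial_force[] <- 0
  lp$lateral_force[] <- 0
  h <- run_activity(fx$cm, fx$st, lp, fx$cfg$control)
  # the first few solves relax the implanted state to the activity
  # tolerance; thereafter the kinematics are exactly constant
  later <- h$node_pos[, , -(1:10), drop = FALSE]
  spread <- apply(later, c(1, 2), function(x) diff(range(x)))
  expect_lt(max(spread), 1e-12)
})

test_that("peak micromotion settles from cycle 3 to cycle 4", {
  fx <- fixture_implanted("PEEK")
  lp <- build_load_profile("squat", bodyweight = fx$patient$weight,
                           n_cycles = 4)
  h <- run_activity(fx$cm, fx$st, lp, fx$cfg$control)
  pk <- vapply(3:4, function(cyc) {
    fl <- micromotion_field(project_and_track(h, cyc), 0.5)
    max(fl$value_um, na.rm = TRUE)
  }, 0)
  expect_lte(pk[2], pk[1] * (1 + 0.05))
})
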