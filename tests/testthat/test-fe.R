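test_that("a single unconstrained elastic tet has six rigid-body modes", {
  m <- volume_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                   matrix(1:4, 1))
  mod <- fe_assemble(m, material_card("elastic", 10, 0.3))
  ev <- eigen(as.matrix(mod$K), symmetric = TRUE, only.values = TRUE)$values
  expect_identical(sum(abs(ev) < 1e-8 * max(ev)), 6L)
  expect_error(fe_solve_elastic(mod, integer(0)), "rigid-body")
})

test_that("the patch test reproduces a constant strain state exactly", {
  p <- benchmark_patch_test()
  expect_lt(p$max_rel_error, 1e-8)
})

test_that("internal force is consistent with the assembled tangent", {
  bm <- mesh_box(2, 1, 1, 3, 2, 2)
  # heterogeneous moduli exercise the per-element constitutive blocks
  ne <- nrow(bm$tets)
  mats <- data.frame(E = seq(1, 20, length.out = ne), nu = 0.3,
                     yield = NA_real_, hardening = 0, material = "bone")
  mod <- fe_assemble(bm, mats)
  set.seed(8)
  u1 <- rnorm(mod$ndof) * 1e-4
  u2 <- rnorm(mod$ndof) * 1e-4
  f1 <- tibiofit:::fe_internal_force(mod, u1, matrix(0, ne, 6), numeric(ne))$f
  f2 <- tibiofit:::fe_internal_force(mod, u2, matrix(0, ne, 6), numeric(ne))$f
  lhs <- f2 - f1
  rhs <- as.numeric(mod$K %*% (u2 - u1))
  expect_lt(max(abs(lhs - rhs)), 1e-9 * max(abs(rhs)))
})

test_that("radial return follows the 1-D closed forms", {
  card <- material_card("bone", 10, 0.3, yield_stress = 80)   # MPa
  mu <- 10 * 1000 / (2 * 1.3)
  # elastic branch: stress equals the elastic prediction exactly
  g_el <- 0.5 * 80 / (sqrt(3) * mu)
  r_el <- radial_return(c(0, 0, 0, g_el, 0, 0), card)
  expect_false(r_el$yielded)
  expect_equal(r_el$stress[4], mu * g_el, tolerance = 1e-12)

  # simple shear past yield, perfect plasticity: q returns to the yield
  # stress, shear stress to sigma_y / sqrt(3)
  g1 <- 3 * 80 / (sqrt(3) * mu)
  r1 <- radial_return(c(0, 0, 0, g1, 0, 0), card)
  expect_true(r1$yielded)
  expect_lt(abs(r1$vm - 80), 1e-8)
  expect_lt(abs(r1$stress[4] - 80 / sqrt(3)), 1e-8)
  expect_gt(r1$alpha, 0)

  # uniaxial strain past yield: axial Von Mises stress at the yield stress
  e1 <- 2 * 80 / (2 * mu)
  ru <- radial_return(c(e1, 0, 0, 0, 0, 0), card)
  expect_true(ru$yielded)
  expect_lt(abs(ru$vm - 80), 1e-8)

  # load-unload cycle: residual plastic strain, reverse elastic slope
  st1 <- list(ep = r1$ep, alpha = r1$alpha)
  dg <- 0.2 * g1
  r2 <- radial_return(c(0, 0, 0, g1 - dg, 0, 0), card, st1)
  expect_false(r2$yielded)
  expect_equal(r1$stress[4] - r2$stress[4], mu * dg, tolerance = 1e-8)
  expect_gt(sum(abs(r2$ep)), 0)
})

test_that("external work equals stored energy on an elastic monotonic ramp", {
  bm <- mesh_box(4, 2, 2, 4, 2, 2)
  mod <- fe_assemble(bm, material_card("elastic", 5, 0.3))
  fixed <- tibiofit:::node_dofs(bm$node_sets$x0)
  tip <- bm$node_sets$x1
  fpat <- numeric(mod$ndof)
  fpat[tibiofit:::node_dofs(tip, 3)] <- -10 / length(tip)
  u_prev <- numeric(mod$ndof)
  W <- 0
  for (k in 1:10) {
    sol <- fe_solve_elastic(mod, fixed, 0, fpat * k / 10)
    W <- W + sum((fpat * (k - 0.5) / 10) * (sol$u - u_prev))
    u_prev <- sol$u
  }
  U <- 0.5 * sum(u_prev * as.numeric(mod$K %*% u_prev))
  expect_lt(abs(W - U) / U, 0.01)
})
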