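test_that("HU-to-density calibration passes through the anchors", {
  a <- calibration_anchors()
  expect_equal(hu_to_density(-1000, a), 0)
  expect_equal(hu_to_density(-100, a), 0.95)
  expect_equal(hu_to_density(40, a), 1.05)
  mid <- (-100 + 40) / 2
  expect_equal(hu_to_density(mid, a), (0.95 + 1.05) / 2, tolerance = 1e-12)
  # below air clamps to zero; above muscle extrapolates linearly
  expect_equal(hu_to_density(-2000, a), 0)
  slope <- (1.05 - 0.95) / 140
  expect_equal(hu_to_density(1040, a), 1.05 + slope * 1000, tolerance = 1e-12)
})

test_that("HU -> density -> modulus composition is monotone over a sweep", {
  a <- calibration_anchors()
  m <- bone_material_map()
  hu <- seq(-1200, 2500, length.out = 10000)
  rho <- hu_to_density(hu, a)
  expect_true(all(diff(rho) >= 0))
  E <- pmin(pmax(m$a * rho^m$b, m$modulus_bounds[1]), m$modulus_bounds[2])
  expect_true(all(diff(E) >= -1e-12))
})

test_that("density-to-card clamps into the bone modulus range", {
  m <- bone_material_map()
  expect_equal(density_to_card(10, m)$youngs_modulus, 20.5)
  expect_equal(density_to_card(0, m)$youngs_modulus, 5.0)
  c1 <- density_to_card(1.0, m); c2 <- density_to_card(1.4, m)
  expect_lt(c1$youngs_modulus, c2$youngs_modulus)
  expect_equal(c1$yield_stress, m$yield_strain * c1$youngs_modulus * 1000,
               tolerance = 1e-12)
  expect_error(material_card("x", 1, 0.3, yield_stress = -5))
})

test_that("implant materials are assigned by component", {
  co <- tiny_cohort()
  cfg <- desk_config()
  rec <- reconstruct_tibia(co[1, ], cfg, seed = 11)
  for (m in c("PEEK", "titanium")) {
    tab <- assign_materials(rec$implant_mesh, m)
    tray <- tab$material == "tray"
    ins <- tab$material == "insert"
    expect_true(all(tab$E[tray] == if (m == "PEEK") 3.7 else 109))
    expect_true(all(tab$E[ins] == 0.974))
    expect_true(all(is.na(tab$yield[tray | ins])))
  }
  tabb <- assign_materials(rec$bone_mesh, "PEEK")
  expect_true(all(tabb$E >= 5.0 - 1e-12 & tabb$E <= 20.5 + 1e-12))
  expect_true(all(tabb$yield > 0))

  bad <- rec$implant_mesh
  bad$element_material[1] <- "ceramic"
  expect_error(assign_materials(bad, "PEEK"), "ceramic")
})
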