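test_that("a unit cube surface tetrahedralizes to the target edge length", {
  cube <- make_cube_surface()
  vm <- tetrahedralize(cube, geometry_config(edge_length = c(0.25, 0.3)))
  expect_true(all(tet_volumes(vm$nodes, vm$tets) > 0))
  med <- stats::median(mesh_edge_lengths(vm))
  expect_gte(med, 0.25)
  expect_lte(med, 0.3)
})

test_that("bone tetrahedralization conserves volume and populates sets", {
  co <- tiny_cohort()
  tib <- generate_tibia(co[1, ], seed = 3, apply_pose_noise = FALSE)
  fr <- assign_frame(tib)
  cfg <- geometry_config(edge_scale = 3)
  cs <- cut_bone(tib, fr, cfg)
  vm <- tetrahedralize(cs, cfg)
  expect_true(all(tet_volumes(vm$nodes, vm$tets) > 0))
  vol_ratio <- sum(tet_volumes(vm$nodes, vm$tets)) / attr(vm, "analytic_volume")
  expect_lt(abs(vol_ratio - 1), 0.02)
  # interface nodes lie exactly on the resection plane; distal set at the cut
  expect_lt(max(abs(vm$nodes[vm$node_sets$interface_bone, 3] - cs$z_prox)), 1e-6)
  expect_lt(max(abs(vm$nodes[vm$node_sets$distal_fixed, 3] - cs$z_dist)), 1e-6)
  expect_gt(length(vm$node_sets$interface_bone), 3)
  expect_gt(length(vm$node_sets$distal_fixed), 3)
  # per-element HU sampled with cortical/trabecular contrast
  expect_gt(max(vm$element_hu), 700)
  expect_lt(min(vm$element_hu), 600)
})

test_that("a bored bone mesh exposes the bore wall; implant mesh its peg", {
  co <- tiny_cohort()
  cfg <- desk_config()
  rec <- reconstruct_tibia(co[1, ], cfg, seed = 11)
  bm <- rec$bone_mesh
  expect_gt(length(bm$node_sets$bore_wall), 5)
  entry <- rec$entry
  r <- sqrt((bm$nodes[bm$node_sets$bore_wall, 1] - rec$selection$placement$translation[1])^2 +
            (bm$nodes[bm$node_sets$bore_wall, 2] - rec$selection$placement$translation[2])^2)
  expect_lt(max(abs(r - entry$peg_radius)), 1e-6)
  im <- rec$implant_mesh
  expect_gt(length(im$node_sets$peg_wall), 5)
  expect_gt(length(im$node_sets$interface_implant), 5)
  expect_lt(max(abs(im$nodes[im$node_sets$interface_implant, 3] - rec$cut$z_prox)), 1e-6)
})

test_that("structured box and tube helpers produce valid meshes", {
  bm <- mesh_box(2, 1, 1, 4, 2, 2)
  expect_true(all(tet_volumes(bm$nodes, bm$tets) > 0))
  expect_equal(sum(tet_volumes(bm$nodes, bm$tets)), 2, tolerance = 1e-12)
  tm <- mesh_tube(5, 10, 4, nr = 3, ntheta = 16, nz = 2)
  expect_true(all(tet_volumes(tm$nodes, tm$tets) > 0))
  v_exact <- pi * (10^2 - 5^2) * 4
  expect_lt(abs(sum(tet_volumes(tm$nodes, tm$tets)) / v_exact - 1), 0.03)
  cy <- mesh_cylinder(5, 4, nr = 3, ntheta = 16, nz = 2)
  expect_lt(abs(sum(tet_volumes(cy$nodes, cy$tets)) / (pi * 25 * 4) - 1), 0.03)
})
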